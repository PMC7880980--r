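#' Calinski-Harabasz score of a labelling
#'
#' The variance-ratio criterion: with g groups among n points, the score is
#' `(B / (g - 1)) / (W / (n - g))`, where B is the between-group dispersion
#' (trace of the between-group scatter, i.e. sum over groups of group size
#' times squared distance of the group mean from the grand mean) and W the
#' within-group dispersion (trace of the pooled within-group scatter).
#' Well-separated tight clusters give large scores; a random labelling gives
#' scores near 1 (the F-ratio null). The trace-based form is used, matching
#' the common reference implementations.
#'
#' @param x Numeric matrix, one row per point.
#' @param labels Vector of group labels, length `nrow(x)`, at least 2
#'   distinct values, each present at least once.
#' @return The score (finite, nonnegative).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (length(labels) != n) stop("`labels` must have one entry per row of `x`")
  f <- factor(labels)
  g <- nlevels(f)
  if (g < 2) stop("need at least 2 distinct labels (got ", g, ")")
  if (n < g + 1) stop("need n > g points")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  total <- sum(xc^2)
  sums <- rowsum(xc, f)
  ng <- as.numeric(table(f))
  between <- sum(sums^2 / ng)
  within <- total - between
  if (within <= .Machine$double.eps * max(total, 1)) {
    stop("zero within-group dispersion: clustering is degenerate-perfect")
  }
  (between / (g - 1)) / (within / (n - g))
}

#' Monte-Carlo random-label baseline for the Calinski-Harabasz score
#'
#' Permutes the observed label multiset uniformly at random (preserving the
#' category sizes — the stricter null) and recomputes the score each time.
#' For any vector configuration the permutation mean tends to 1 as n grows.
#'
#' @param x Numeric matrix of points.
#' @param labels Observed labels (their multiset is what gets permuted).
#' @param n_iterations Number of permutations (default 1000).
#' @param seed RNG seed; the same seed reproduces the same (mean, sd).
#' @return List with `mean`, `sd` (`NA` with a warning when
#'   `n_iterations == 1`), `n_iterations`, `seed`.
#' @export
random_label_baseline <- function(x, labels, n_iterations = 1000L, seed = 1L) {
  x <- as.matrix(x)
  f <- factor(as.character(labels))
  g <- nlevels(f)
  n <- nrow(x)
  if (g < 2) stop("need at least 2 distinct labels")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  total <- sum(xc^2)
  ng <- as.numeric(table(f))
  scores <- with_seed_(seed, {
    vapply(seq_len(n_iterations), function(i) {
      fp <- f[sample.int(n)]
      between <- sum(rowsum(xc, fp)^2 / ng)
      within <- total - between
      (between / (g - 1)) / (within / (n - g))
    }, numeric(1))
  })
  s <- if (n_iterations > 1) sd(scores) else {
    warning("sd undefined for a single iteration; reporting NA")
    NA_real_
  }
  list(mean = mean(scores), sd = s,
       n_iterations = as.integer(n_iterations), seed = as.integer(seed))
}

new_cluster_diagnostic <- function(ch, n_points, n_labels, baseline,
                                   what = NULL, extra = list()) {
  structure(
    c(list(ch_score = ch, n_points = as.integer(n_points),
           n_labels = as.integer(n_labels),
           baseline_mean = baseline$mean, baseline_sd = baseline$sd,
           n_iterations = baseline$n_iterations, seed = baseline$seed,
           what = what), extra),
    class = "cluster_diagnostic"
  )
}

#' @export
print.cluster_diagnostic <- function(x, ...) {
  cat("<cluster_diagnostic>", if (!is.null(x$what)) paste0(" ", x$what), "\n",
      "  CH = ", signif(x$ch_score, 5), " over ", x$n_points, " points, ",
      x$n_labels, " labels\n",
      "  random-label baseline: M = ", signif(x$baseline_mean, 4),
      ", SD = ", signif(x$baseline_sd, 3), " (", x$n_iterations,
      " iterations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @method tidy cluster_diagnostic
#' @export
tidy.cluster_diagnostic <- function(x, ...) {
  tibble(ch_score = x$ch_score, n_points = x$n_points, n_labels = x$n_labels,
         baseline_mean = x$baseline_mean, baseline_sd = x$baseline_sd,
         n_iterations = x$n_iterations, seed = x$seed)
}

#' @method glance cluster_diagnostic
#' @export
glance.cluster_diagnostic <- function(x, ...) tidy(x)

#' Write a diagnostic report as JSON
#'
#' @param diag A `cluster_diagnostic`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_diagnostic <- function(diag, path) {
  stopifnot(inherits(diag, "cluster_diagnostic"))
  jsonlite::write_json(
    list(ch = diag$ch_score, baseline_mean = diag$baseline_mean,
         baseline_sd = diag$baseline_sd, n = diag$n_points,
         g = diag$n_labels, iterations = diag$n_iterations, seed = diag$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cluster separability of one word's labelled contexts
#'
#' Samples a fraction of the contexts containing `word` (without
#' replacement, seeded, so the irreproducible step of labelling a manual
#' sample becomes reproducible), scores the supplied meaning/category labels
#' on the sampled context vectors with [calinski_harabasz()], and attaches
#' the random-permutation baseline. A score far above the baseline means the
#' context vectors separate the labelled categories; a score within the
#' baseline means they do not.
#'
#' @param space A `semantic_space`.
#' @param word A vocabulary word.
#' @param context_labels Labels for the word's contexts: a named vector or a
#'   two-column data frame (`context_id`, `label`), keyed by context id.
#' @param fraction Fraction of the word's contexts to sample (default 0.5;
#'   1.0 uses all).
#' @param n_iterations Baseline permutations.
#' @param seed Seed for both the sampling and the baseline.
#' @return A `cluster_diagnostic`.
#' @export
word_context_diagnostic <- function(space, word, context_labels,
                                    fraction = 0.5, n_iterations = 1000L,
                                    seed = 1L) {
  stopifnot(inherits(space, "semantic_space"),
            fraction > 0, fraction <= 1)
  if (!word %in% names(space$word_contexts)) {
    stop("word not in vocabulary: ", word)
  }
  if (is.data.frame(context_labels)) {
    context_labels <- stats::setNames(as.character(context_labels[[2]]),
                                      as.character(context_labels[[1]]))
  }
  rows <- space$word_contexts[[word]]
  ids <- as.character(space$context_ids[rows])
  n <- length(rows)
  take <- ceiling(fraction * n)
  sel <- with_seed_(seed, sort(sample.int(n, take)))
  ids <- ids[sel]
  missing <- !ids %in% names(context_labels)
  if (any(missing)) {
    stop(sum(missing), " sampled context(s) of '", word, "' have no label")
  }
  labs <- unname(context_labels[ids])
  if (length(unique(labs)) < 2) {
    stop("sampled contexts of '", word, "' carry fewer than 2 distinct labels")
  }
  v <- context_vectors(space)[rows[sel], , drop = FALSE]
  ch <- calinski_harabasz(v, labs)
  base <- random_label_baseline(v, labs, n_iterations = n_iterations, seed = seed)
  new_cluster_diagnostic(ch, nrow(v), length(unique(labs)), base,
                         what = paste0("word '", word, "' (fraction ",
                                       fraction, ")"))
}

#' Cluster separability of the whole corpus by a metadata dimension
#'
#' Groups every context vector by one document-metadata dimension (e.g.
#' `domain` or `medium`) and scores the grouping with
#' [calinski_harabasz()] plus its random-label baseline. Contexts with a
#' missing label are excluded, with a message reporting how many.
#'
#' @param space A `semantic_space` whose context metadata carries the
#'   dimension.
#' @param label_dimension Name of the metadata column.
#' @param n_iterations Baseline permutations.
#' @param seed Seed for the baseline.
#' @return A `cluster_diagnostic`.
#' @export
corpus_label_diagnostic <- function(space, label_dimension,
                                    n_iterations = 1000L, seed = 1L) {
  stopifnot(inherits(space, "semantic_space"))
  meta <- space$context_meta
  if (!label_dimension %in% names(meta)) {
    stop("no metadata column '", label_dimension, "'")
  }
  labs <- as.character(meta[[label_dimension]])
  keep <- !is.na(labs)
  if (any(!keep)) {
    message(sum(!keep), " context(s) without a '", label_dimension,
            "' label excluded")
  }
  if (length(unique(labs[keep])) < 2) {
    stop("metadata dimension '", label_dimension,
         "' has fewer than 2 categories")
  }
  v <- context_vectors(space)[keep, , drop = FALSE]
  ch <- calinski_harabasz(v, labs[keep])
  base <- random_label_baseline(v, labs[keep], n_iterations = n_iterations,
                                seed = seed)
  new_cluster_diagnostic(ch, nrow(v), length(unique(labs[keep])), base,
                         what = paste0("corpus by '", label_dimension, "'"))
}

#' Two-dimensional t-SNE embedding of labelled vectors
#'
#' Exact t-SNE (Gaussian input affinities calibrated to the target
#' perplexity by per-point binary search; Student-t output affinities;
#' gradient descent on the KL divergence with momentum and early
#' exaggeration). Quadratic in n, intended for the corpus sizes this package
#' works at; the embedding is a visual aid, and no quantitative result in
#' the package depends on its geometry.
#'
#' @param x Numeric matrix of points (n >= 5).
#' @param labels Optional vector of labels carried into the output.
#' @param perplexity Target perplexity (must be < n; default
#'   `min(30, (n - 1) / 3)`).
#' @param seed RNG seed; the same seed gives identical coordinates.
#' @param n_iter Gradient-descent iterations (default 400).
#' @return Tibble of class `tsne_embedding`: `dim1`, `dim2`, `label`.
#' @export
embed_2d <- function(x, labels = NULL, perplexity = NULL, seed = 1L,
                     n_iter = 400L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 points")
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  if (perplexity >= n) stop("perplexity must be smaller than the number of points")
  if (!is.null(labels) && length(labels) != n) {
    stop("`labels` must have one entry per row")
  }
  p <- tsne_affinities(x, perplexity)
  y <- with_seed_(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  y <- tsne_descend(p, y, n_iter = n_iter)
  out <- tibble(dim1 = y[, 1], dim2 = y[, 2],
                label = if (is.null(labels)) NA_character_ else as.character(labels))
  class(out) <- c("tsne_embedding", class(out))
  out
}

# Symmetrised input affinities at the target perplexity.
tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  log_perp <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:60) {
      w <- exp(-di * beta)
      w[i] <- 0
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      h <- log(sw) + beta * sum(di[w > 0] * w[w > 0]) / sw
      if (abs(h - log_perp) < 1e-7) break
      if (h > log_perp) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, ] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

# KL gradient descent with momentum and early exaggeration.
tsne_descend <- function(p, y, n_iter = 400L, lr = 100) {
  n <- nrow(y)
  inc <- matrix(0, n, 2)
  exag_until <- min(100L, n_iter %/% 4L)
  p_run <- p * 4
  for (it in seq_len(n_iter)) {
    if (it == exag_until + 1L) p_run <- p
    sq <- rowSums(y^2)
    num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(y))
    diag(num) <- 0
    q <- num / sum(num)
    q <- pmax(q, 1e-12)
    l <- (p_run - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    mom <- if (it < 250) 0.5 else 0.8
    inc <- mom * inc - lr * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

#' Scatter plot of a 2-D embedding
#'
#' @param object A `tsne_embedding` from [embed_2d()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tsne_embedding
#' @export
autoplot.tsne_embedding <- function(object, ...) {
  df <- as_tibble(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (!all(is.na(df$label))) {
    pl <- pl + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                                   alpha = 0.8)
  } else {
    pl <- pl + ggplot2::geom_point(alpha = 0.8)
  }
  pl + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") + ggplot2::theme_minimal()
}
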