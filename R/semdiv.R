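#' Semantic diversity of a single word
#'
#' SemD is the negative log of the mean pairwise cosine similarity among the
#' context vectors of all contexts containing the word: every unordered pair
#' of distinct contexts contributes one cosine, each context counts once
#' regardless of how often the word occurs within it, and the mean is
#' transformed as `semd = -log(mean_cosine)`. Identical contexts give
#' SemD = 0; the more mutually dissimilar the contexts, the higher the
#' value.
#'
#' Contexts whose vectors are numerically zero after truncation are excluded
#' from the pair set (their cosine is undefined) and counted in
#' `n_excluded`. A word with fewer than 2 usable contexts, or a nonpositive
#' mean cosine, yields `NA` with an explanatory `status` rather than a
#' clamped value — a fabricated score would be worse than a missing one.
#'
#' @param space A `semantic_space`.
#' @param word A vocabulary word.
#' @param log_base Base of the log transform (default natural log; the base
#'   only rescales SemD linearly).
#' @return One-row tibble: `word`, `n_contexts` (usable), `n_excluded`,
#'   `mean_cosine`, `semd`, `status` (`"ok"`, `"too_few_contexts"`, or
#'   `"nonpositive_mean"`).
#' @export
#' @examples
#' # see semdiv_table() for scoring in batch
semantic_diversity <- function(space, word, log_base = exp(1)) {
  stopifnot(inherits(space, "semantic_space"), length(word) == 1)
  if (!word %in% names(space$word_contexts)) {
    stop("word not in vocabulary: ", word)
  }
  rows <- space$word_contexts[[word]]
  v <- context_vectors(space)[rows, , drop = FALSE]
  norms <- sqrt(rowSums(v^2))
  usable <- norms > 1e-12
  n_excluded <- sum(!usable)
  v <- v[usable, , drop = FALSE]
  n <- nrow(v)
  if (n < 2) {
    return(tibble(word = word, n_contexts = n, n_excluded = n_excluded,
                  mean_cosine = NA_real_, semd = NA_real_,
                  status = "too_few_contexts"))
  }
  u <- v / norms[usable]
  # mean over the C(n,2) unordered pairs: ||sum u||^2 = n + 2 * sum_{i<j} u_i.u_j
  s <- colSums(u)
  mean_cos <- (sum(s^2) - n) / (n * (n - 1))
  if (mean_cos <= 0) {
    return(tibble(word = word, n_contexts = n, n_excluded = n_excluded,
                  mean_cosine = mean_cos, semd = NA_real_,
                  status = "nonpositive_mean"))
  }
  tibble(word = word, n_contexts = n, n_excluded = n_excluded,
         mean_cosine = mean_cos, semd = -log(mean_cos, base = log_base),
         status = "ok")
}

#' Semantic diversity for a set of words
#'
#' Batch form of [semantic_diversity()]: one row per requested word, in
#' request order (duplicates are dropped with a warning, never silently;
#' missing values are flagged in `status`, never dropped).
#'
#' @param space A `semantic_space`.
#' @param words Character vector of words to score; default all vocabulary
#'   words.
#' @param log_base Base of the log transform.
#' @return Tibble of class `semdiv_tbl`, one row per unique word.
#' @export
semdiv_table <- function(space, words = NULL, log_base = exp(1)) {
  stopifnot(inherits(space, "semantic_space"))
  if (is.null(words)) words <- names(space$word_contexts)
  if (anyDuplicated(words)) {
    warning("duplicate words in request; scoring each once")
    words <- unique(words)
  }
  unknown <- setdiff(words, names(space$word_contexts))
  known <- setdiff(words, unknown)
  rows <- lapply(known, function(w) semantic_diversity(space, w, log_base))
  out <- bind_rows(rows)
  if (length(unknown)) {
    out <- bind_rows(out, tibble(word = unknown, n_contexts = 0L,
                                 n_excluded = 0L, mean_cosine = NA_real_,
                                 semd = NA_real_, status = "unknown_word"))
  }
  out <- out[match(words, out$word), , drop = FALSE]
  class(out) <- c("semdiv_tbl", class(out))
  out
}

#' Write a SemD table to TSV
#'
#' @param tbl Output of [semdiv_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_semdiv <- function(tbl, path) {
  readr::write_tsv(as_tibble(tbl), path)
  invisible(path)
}

#' Histogram of a SemD table
#'
#' @param object A `semdiv_tbl`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot semdiv_tbl
#' @export
autoplot.semdiv_tbl <- function(object, bins = 30, ...) {
  df <- filter(as_tibble(object), .data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$semd)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "semantic diversity (SemD)", y = "words") +
    ggplot2::theme_minimal()
}

#' Correlate two SemD tables (e.g. scaled vs unscaled variants)
#'
#' Pearson and Spearman correlations of `semd` over the words shared by the
#' two tables with finite values in both. At least 3 shared finite words are
#' required.
#'
#' @param table_a,table_b Outputs of [semdiv_table()].
#' @return Object of class `semdiv_comparison` with `n_shared`, `pearson_r`,
#'   `spearman_rho`; [tidy()] and [glance()] return it as a tibble.
#' @export
compare_variants <- function(table_a, table_b) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b))
  a <- filter(as_tibble(table_a), is.finite(.data$semd))
  b <- filter(as_tibble(table_b), is.finite(.data$semd))
  shared <- intersect(a$word, b$word)
  if (length(shared) < 3) {
    stop("fewer than 3 shared words with finite SemD (", length(shared), ")")
  }
  x <- a$semd[match(shared, a$word)]
  y <- b$semd[match(shared, b$word)]
  structure(
    list(n_shared = length(shared),
         pearson_r = cor(x, y, method = "pearson"),
         spearman_rho = cor(x, y, method = "spearman")),
    class = "semdiv_comparison"
  )
}

#' @export
print.semdiv_comparison <- function(x, ...) {
  cat("<semdiv_comparison> n = ", x$n_shared,
      ", Pearson r = ", signif(x$pearson_r, 4),
      ", Spearman rho = ", signif(x$spearman_rho, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy semdiv_comparison
#' @export
tidy.semdiv_comparison <- function(x, ...) {
  tibble(method = c("pearson", "spearman"),
         estimate = c(x$pearson_r, x$spearman_rho),
         n = x$n_shared)
}

#' @method glance semdiv_comparison
#' @export
glance.semdiv_comparison <- function(x, ...) {
  tibble(n_shared = x$n_shared, pearson_r = x$pearson_r,
         spearman_rho = x$spearman_rho)
}
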