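# Shared fixtures and independent oracles used across the suite.

# Build a chunk tibble directly from token lists (bypasses text I/O).
make_chunks <- function(token_lists, doc_ids = NULL, labels = NULL) {
  n <- length(token_lists)
  out <- tibble::tibble(
    context_id = seq_len(n),
    doc_id = if (is.null(doc_ids)) sprintf("d%03d", seq_len(n)) else doc_ids,
    n_tokens = lengths(token_lists),
    tokens = token_lists
  )
  if (!is.null(labels)) out <- dplyr::bind_cols(out, labels)
  class(out) <- c("semdiv_chunks", class(out))
  out
}

# Build a semantic_space directly from a context-vector matrix.
make_raw_space <- function(vectors, word_contexts, scaled = FALSE,
                           d = NULL, meta = NULL) {
  vectors <- as.matrix(vectors)
  vocab <- tibble::tibble(word = names(word_contexts),
                          count = lengths(word_contexts),
                          context_count = lengths(word_contexts),
                          index = seq_along(word_contexts))
  class(vocab) <- c("semdiv_vocab", class(vocab))
  structure(
    list(u = vectors,
         d = if (is.null(d)) rep(1, ncol(vectors)) else d,
         k = ncol(vectors), scaled = scaled,
         word_contexts = word_contexts, vocab = vocab,
         context_ids = seq_len(nrow(vectors)),
         context_meta = if (is.null(meta)) {
           tibble::tibble(context_id = seq_len(nrow(vectors)),
                          doc_id = sprintf("d%03d", seq_len(nrow(vectors))))
         } else meta),
    class = "semantic_space"
  )
}

# Brute-force mean pairwise cosine over all unordered pairs.
oracle_mean_cosine <- function(v) {
  n <- nrow(v)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(v[i, ] * v[j, ]) /
        (sqrt(sum(v[i, ]^2)) * sqrt(sum(v[j, ]^2)))
    }
  }
  tot / choose(n, 2)
}

# Direct trace-ratio evaluation of the variance-ratio criterion: explicit
# per-group deviations, no shared code with calinski_harabasz().
oracle_ch <- function(x, labels) {
  x <- as.matrix(x)
  f <- factor(labels)
  g <- nlevels(f)
  n <- nrow(x)
  mu <- colMeans(x)
  between <- 0
  within <- 0
  for (lv in levels(f)) {
    xi <- x[f == lv, , drop = FALSE]
    mi <- colMeans(xi)
    between <- between + nrow(xi) * sum((mi - mu)^2)
    within <- within + sum(sweep(xi, 2, mi)^2)
  }
  (between / (g - 1)) / (within / (n - g))
}

# Independent SVD oracle: eigen-decomposition of the Gram matrix (a
# different algorithmic route than the LAPACK bidiagonalisation the
# implementation uses).
oracle_svd <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) >= ncol(a)) {
    e <- eigen(crossprod(a), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    list(d = d, v = e$vectors)
  } else {
    e <- eigen(tcrossprod(a), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    list(d = d, u = e$vectors)
  }
}

# Direct log-entropy evaluation, straight from the formula.
oracle_log_entropy <- function(counts, base = exp(1)) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  w <- matrix(0, n, ncol(counts))
  g <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    p <- counts[, j] / sum(counts[, j])
    ent <- sum(ifelse(p > 0, p * log(p), 0))
    g[j] <- 1 + ent / log(n)
    w[, j] <- g[j] * log(1 + counts[, j], base = base)
  }
  list(g = g, w = w)
}

# Tiny two-word toy corpus used by several files.
toy_chunks <- function() {
  make_chunks(list(
    c("run", "run", "bank", "tree"),
    c("bank", "tree", "tree", "fish"),
    c("run", "fish", "fish", "tree")
  ))
}
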