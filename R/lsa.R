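#' Truncated singular value decomposition
#'
#' Computes the leading `k` singular triplets of the weighted matrix via
#' LAPACK's dense SVD, which is exact and deterministic at the problem sizes
#' this package targets (`seed` is accepted for interface stability but has
#' no effect on the result). If `k` exceeds the numerical rank it is capped
#' with a warning.
#'
#' @param w A `weighted_matrix` (or any numeric matrix).
#' @param k Number of dimensions to keep (default 300).
#' @param seed Unused by the dense backend; kept so configs that record a
#'   seed remain reproducible descriptions of a run.
#' @param rank_tol Relative tolerance for the rank cap (default 1e-10 times
#'   the leading singular value).
#' @return Object of class `svd_result`: list with `u` (n x k), `d`
#'   (length-k nonincreasing singular values), `v` (m x k), `k`.
#' @export
truncated_svd <- function(w, k = 300L, seed = 1L, rank_tol = 1e-10) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer")
  a <- if (inherits(w, "weighted_matrix")) as.matrix(w$values) else as.matrix(w)
  s <- svd(a)
  rank <- sum(s$d > rank_tol * max(s$d[1], .Machine$double.eps))
  rank <- max(rank, 1L)
  kmax <- min(nrow(a), ncol(a))
  if (k > rank) {
    warning("k = ", k, " exceeds matrix rank ", rank, "; capped")
    k <- rank
  }
  k <- min(k, kmax)
  structure(
    list(u = s$u[, seq_len(k), drop = FALSE],
         d = s$d[seq_len(k)],
         v = s$v[, seq_len(k), drop = FALSE],
         k = k),
    class = "svd_result"
  )
}

#' Assemble the semantic space of context vectors
#'
#' Builds the n x k context-vector matrix from a truncated SVD. With
#' `scaled = TRUE` (the classical LSA output) the vectors are the rows of
#' `U %*% diag(d)`; with `scaled = FALSE` they are the rows of `U` alone —
#' the variant one obtains by forgetting to weight the singular vectors by
#' the singular values. Both variants are first-class because published SemD
#' norms appear to differ on exactly this choice; [set_scaling()] flips
#' between them without recomputation.
#'
#' The word-to-context index maps each vocabulary word to the rows of the
#' contexts containing it (count >= 1 in the count matrix).
#'
#' @param svd_res An `svd_result` from [truncated_svd()].
#' @param cooc The `cooc_matrix` the SVD was computed from (supplies the
#'   word-to-context index and context metadata).
#' @param scaled Scale singular vectors by singular values? Default `TRUE`.
#' @return Object of class `semantic_space`: list with `u`, `d`, `k`,
#'   `scaled`, `word_contexts` (named list of row indices), `vocab`,
#'   `context_ids`, `context_meta`.
#' @export
make_space <- function(svd_res, cooc, scaled = TRUE) {
  stopifnot(inherits(svd_res, "svd_result"), inherits(cooc, "cooc_matrix"))
  if (nrow(svd_res$u) != nrow(cooc$counts)) {
    stop("svd and count matrix disagree on the number of contexts")
  }
  cc <- methods::as(cooc$counts, "CsparseMatrix")
  jj <- rep.int(seq_len(ncol(cc)), diff(cc@p))
  word_contexts <- split(cc@i + 1L, factor(jj, levels = seq_len(ncol(cc))))
  names(word_contexts) <- colnames(cc)
  word_contexts <- lapply(word_contexts, sort)
  structure(
    list(u = svd_res$u, d = svd_res$d, k = svd_res$k,
         scaled = isTRUE(scaled),
         word_contexts = word_contexts,
         vocab = cooc$vocab,
         context_ids = cooc$context_ids,
         context_meta = cooc$context_meta),
    class = "semantic_space"
  )
}

#' Extract the context-vector matrix of a space
#'
#' @param space A `semantic_space`.
#' @return Dense n x k matrix of context vectors, honouring the space's
#'   `scaled` flag.
#' @export
context_vectors <- function(space) {
  stopifnot(inherits(space, "semantic_space"))
  if (space$scaled) sweep(space$u, 2, space$d, `*`) else space$u
}

#' Switch a space between scaled and unscaled variants
#'
#' @param space A `semantic_space`.
#' @param scaled New value of the scaling flag.
#' @return The space with the flag set.
#' @export
set_scaling <- function(space, scaled) {
  stopifnot(inherits(space, "semantic_space"))
  space$scaled <- isTRUE(scaled)
  space
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("<semantic_space> ", nrow(x$u), " contexts x k = ", x$k,
      if (x$scaled) " (scaled by singular values)" else " (unscaled singular vectors)",
      "; ", length(x$word_contexts), " words\n", sep = "")
  invisible(x)
}

#' Run the full corpus-to-space pipeline
#'
#' Convenience wrapper: [chunk_documents()] -> [build_vocabulary()] ->
#' [build_cooc()] -> [log_entropy_weight()] -> [truncated_svd()] ->
#' [make_space()]. Defaults are the classical settings for SemD: 1000-word
#' contexts, count threshold 50, context threshold 40, k = 300, scaled
#' vectors.
#'
#' @param docs Document tibble from [read_corpus()].
#' @param window Context length in cleaned tokens.
#' @param config A [clean_config()].
#' @param min_count,min_contexts Vocabulary thresholds.
#' @param k SVD dimensionality.
#' @param scaled Scale singular vectors by singular values?
#' @param seed Recorded and passed to [truncated_svd()].
#' @param clean_first,drop_final_always,rule Passed through to
#'   [chunk_documents()] and [build_vocabulary()].
#' @return A `semantic_space`.
#' @export
build_semantic_space <- function(docs, window = 1000L, config = clean_config(),
                                 min_count = 50L, min_contexts = 40L,
                                 k = 300L, scaled = TRUE, seed = 1L,
                                 clean_first = TRUE, drop_final_always = FALSE,
                                 rule = "both") {
  chunks <- chunk_documents(docs, window = window, config = config,
                            clean_first = clean_first,
                            drop_final_always = drop_final_always)
  vocab <- build_vocabulary(chunks, min_count = min_count,
                            min_contexts = min_contexts, rule = rule)
  if (nrow(vocab) == 0) stop("vocabulary is empty after thresholding")
  cooc <- build_cooc(chunks, vocab)
  w <- log_entropy_weight(cooc)
  sv <- truncated_svd(w, k = k, seed = seed)
  make_space(sv, cooc, scaled = scaled)
}

#' Persist / load a semantic space as plain-text files
#'
#' `write_space()` writes `u.tsv`, `d.tsv`, `vocab.tsv`, `contexts.tsv`,
#' `word_contexts.tsv` (long word/row pairs) and `meta.json` (k, scaled,
#' seed if recorded) into `dir`; `read_space()` reconstructs the space, so
#' either scaling variant can be derived after the fact.
#'
#' @param space A `semantic_space`.
#' @param dir Directory (created if needed).
#' @param seed Optional seed to record in the metadata.
#' @return `dir` invisibly (write); a `semantic_space` (read).
#' @export
write_space <- function(space, dir, seed = NULL) {
  stopifnot(inherits(space, "semantic_space"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(space$u, file.path(dir, "u.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  writeLines(format(space$d, digits = 17), file.path(dir, "d.tsv"))
  write_vocabulary(space$vocab, file.path(dir, "vocab.tsv"))
  readr::write_tsv(space$context_meta, file.path(dir, "contexts.tsv"))
  wc <- tibble(
    word = rep(names(space$word_contexts), lengths(space$word_contexts)),
    row = unlist(space$word_contexts, use.names = FALSE)
  )
  readr::write_tsv(wc, file.path(dir, "word_contexts.tsv"))
  meta <- list(k = space$k, scaled = space$scaled, seed = seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname write_space
#' @export
read_space <- function(dir) {
  u <- as.matrix(utils::read.table(file.path(dir, "u.tsv"), sep = "\t"))
  dimnames(u) <- NULL
  d <- as.numeric(readLines(file.path(dir, "d.tsv")))
  vocab <- readr::read_tsv(file.path(dir, "vocab.tsv"), show_col_types = FALSE)
  class(vocab) <- c("semdiv_vocab", class(vocab))
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  ctx <- readr::read_tsv(file.path(dir, "contexts.tsv"), show_col_types = FALSE)
  wc_long <- readr::read_tsv(file.path(dir, "word_contexts.tsv"),
                             show_col_types = FALSE)
  word_contexts <- split(wc_long$row, factor(wc_long$word, levels = vocab$word))
  structure(
    list(u = u, d = d, k = as.integer(meta$k), scaled = isTRUE(meta$scaled),
         word_contexts = word_contexts, vocab = vocab,
         context_ids = ctx$context_id, context_meta = ctx),
    class = "semantic_space"
  )
}

#' Singular-value spectrum of a space
#'
#' @param x A `semantic_space`.
#' @param ... Unused.
#' @return Tibble with `component`, `singular_value`, and the share of
#'   retained squared singular value (`prop_retained`).
#' @method tidy semantic_space
#' @export
tidy.semantic_space <- function(x, ...) {
  tibble(component = seq_along(x$d),
         singular_value = x$d,
         prop_retained = x$d^2 / sum(x$d^2))
}

#' One-row summary of a space
#'
#' @param x A `semantic_space`.
#' @param ... Unused.
#' @return Tibble with `n_contexts`, `n_words`, `k`, `scaled`.
#' @method glance semantic_space
#' @export
glance.semantic_space <- function(x, ...) {
  tibble(n_contexts = nrow(x$u), n_words = length(x$word_contexts),
         k = x$k, scaled = x$scaled)
}

#' Scree plot of a space's singular values
#'
#' @param object A `semantic_space`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot semantic_space
#' @export
autoplot.semantic_space <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$singular_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "component", y = "singular value",
                  title = "Singular-value spectrum") +
    ggplot2::theme_minimal()
}
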