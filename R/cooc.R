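#' Build the context-by-word count matrix
#'
#' Rows are contexts, columns are retained vocabulary words; entry (i, j) is
#' the frequency of word j in context i. Tokens outside the vocabulary are
#' skipped. Contexts containing no vocabulary word are kept as empty rows
#' (and counted in a message) so row indexing stays aligned with the chunk
#' manifest.
#'
#' @param chunks Chunk tibble from [chunk_documents()].
#' @param vocab Vocabulary from [build_vocabulary()].
#' @return Object of class `cooc_matrix`: list with `counts` (a sparse
#'   [Matrix::dgCMatrix-class], dimnames = context ids x words), `context_ids`,
#'   `vocab`, and `context_meta` (the chunk manifest columns).
#' @export
build_cooc <- function(chunks, vocab) {
  stopifnot(is.data.frame(chunks), nrow(chunks) > 0, inherits(vocab, "semdiv_vocab"))
  m <- nrow(vocab)
  idx <- stats::setNames(vocab$index, vocab$word)
  triplets <- lapply(seq_len(nrow(chunks)), function(i) {
    j <- idx[chunks$tokens[[i]]]
    j <- j[!is.na(j)]
    if (length(j) == 0) return(NULL)
    tt <- table(j)
    cbind(i = i, j = as.integer(names(tt)), x = as.integer(tt))
  })
  n_empty <- sum(vapply(triplets, is.null, logical(1)))
  if (n_empty > 0) {
    message(n_empty, " context(s) contain no vocabulary word (kept as empty rows)")
  }
  trip <- do.call(rbind, triplets)
  counts <- Matrix::sparseMatrix(
    i = if (is.null(trip)) integer() else trip[, "i"],
    j = if (is.null(trip)) integer() else trip[, "j"],
    x = if (is.null(trip)) numeric() else as.numeric(trip[, "x"]),
    dims = c(nrow(chunks), m),
    dimnames = list(as.character(chunks$context_id), vocab$word)
  )
  meta <- select(as_tibble(chunks), -"tokens")
  structure(
    list(counts = counts, context_ids = chunks$context_id,
         vocab = vocab, context_meta = meta),
    class = "cooc_matrix"
  )
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat("<cooc_matrix> ", nrow(x$counts), " contexts x ", ncol(x$counts),
      " words; ", length(x$counts@x), " nonzero cells\n", sep = "")
  invisible(x)
}

#' Apply log-entropy weighting to a count matrix
#'
#' The standard LSA weighting (Berry, Dumais & O'Brien convention): each
#' cell is the product of a local weight `log(1 + f_ij)` and a global word
#' weight `g_j = 1 + sum_i p_ij log(p_ij) / log(n)`, where
#' `p_ij = f_ij / sum_i f_ij` is word j's distribution over the n contexts.
#' `g_j` is 1 for a word confined to a single context and tends to 0 for a
#' word spread uniformly over all contexts, so it up-weights topically
#' concentrated words. Zero cells stay zero.
#'
#' The logarithm base only rescales the whole matrix by a constant
#' (`g_j` is a ratio of logs and hence base-invariant), so every downstream
#' cosine — and therefore SemD — is unchanged by `base`.
#'
#' @param m A `cooc_matrix` from [build_cooc()].
#' @param base Logarithm base for the local weight (default natural log).
#' @return Object of class `weighted_matrix`: list with `values` (sparse
#'   matrix, same shape), `global_weights` (named numeric, one per word),
#'   `base`, plus the `cooc_matrix` metadata.
#' @export
log_entropy_weight <- function(m, base = exp(1)) {
  stopifnot(inherits(m, "cooc_matrix"))
  counts <- m$counts
  n <- nrow(counts)
  if (n < 2) stop("log-entropy weighting needs at least 2 contexts")
  col_tot <- Matrix::colSums(counts)
  if (any(col_tot == 0)) {
    stop("word(s) with zero total count: ",
         paste(head(colnames(counts)[col_tot == 0], 5), collapse = ", "))
  }
  # entropy term computed on the nonzero cells of the CSC representation
  cc <- methods::as(counts, "CsparseMatrix")
  jj <- rep.int(seq_len(ncol(cc)), diff(cc@p))
  p <- cc@x / col_tot[jj]
  ent <- rowsum(p * log(p), jj)[, 1]            # sum_i p log p, per column
  g <- 1 + as.numeric(ent) / log(n)
  g <- stats::setNames(pmin(pmax(g, 0), 1), colnames(counts))
  w <- cc
  w@x <- log1p(cc@x) / log(base) * g[jj]
  structure(
    list(values = w, global_weights = g, base = base,
         context_ids = m$context_ids, vocab = m$vocab,
         context_meta = m$context_meta),
    class = "weighted_matrix"
  )
}

#' @export
print.weighted_matrix <- function(x, ...) {
  cat("<weighted_matrix> log-entropy, ", nrow(x$values), " contexts x ",
      ncol(x$values), " words (log base ", signif(x$base, 4), ")\n", sep = "")
  invisible(x)
}

#' Write / read a count matrix as Matrix Market + sidecar TSVs
#'
#' `write_cooc()` writes `counts.mtx`, `contexts.tsv` (the chunk manifest)
#' and `vocab.tsv` into `dir`; `read_cooc()` reconstructs the object.
#'
#' @param m A `cooc_matrix`.
#' @param dir Directory (created if needed).
#' @return `dir` invisibly (write); a `cooc_matrix` (read).
#' @export
write_cooc <- function(m, dir) {
  stopifnot(inherits(m, "cooc_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "counts.mtx"))
  readr::write_tsv(m$context_meta, file.path(dir, "contexts.tsv"))
  write_vocabulary(m$vocab, file.path(dir, "vocab.tsv"))
  invisible(dir)
}

#' @rdname write_cooc
#' @export
read_cooc <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  meta <- readr::read_tsv(file.path(dir, "contexts.tsv"), show_col_types = FALSE)
  vocab <- readr::read_tsv(file.path(dir, "vocab.tsv"), show_col_types = FALSE)
  class(vocab) <- c("semdiv_vocab", class(vocab))
  dimnames(counts) <- list(as.character(meta$context_id), vocab$word)
  structure(
    list(counts = counts, context_ids = meta$context_id,
         vocab = vocab, context_meta = meta),
    class = "cooc_matrix"
  )
}
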