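#' Read a corpus of documents
#'
#' Reads either a directory of UTF-8 `.txt` files (one document per file,
#' `doc_id` = file name without extension, lexicographic order) or a JSONL
#' file (one document per line with fields `id`, `text` and an optional
#' `labels` object, line order preserved). Label dimensions (e.g. `domain`,
#' `medium`) become columns of the returned tibble.
#'
#' @param path Directory of `.txt` files, or path to a `.jsonl` file.
#' @param format `"auto"` (directory -> plain, file -> jsonl), `"plain"`, or
#'   `"jsonl"`.
#' @return A tibble with columns `doc_id`, `text`, plus one column per label
#'   dimension present.
#' @export
read_corpus <- function(path, format = c("auto", "plain", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "plain" else "jsonl"
  }
  if (format == "plain") {
    if (!dir.exists(path)) stop("corpus directory not found: ", path)
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0) {
      warning("no .txt files found in ", path)
      return(tibble(doc_id = character(), text = character()))
    }
    texts <- vapply(files, function(f) {
      txt <- tryCatch(readLines(f, warn = FALSE, encoding = "UTF-8"),
                      error = function(e) stop("unreadable file: ", f, " (",
                                               conditionMessage(e), ")",
                                               call. = FALSE))
      paste(txt, collapse = "\n")
    }, character(1))
    docs <- tibble(doc_id = tools::file_path_sans_ext(basename(files)),
                   text = unname(texts))
  } else {
    if (!file.exists(path)) stop("corpus file not found: ", path)
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warning("no documents in ", path)
      return(tibble(doc_id = character(), text = character()))
    }
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) stop("malformed JSONL at line ", i,
                                               ": ", conditionMessage(e),
                                               call. = FALSE))
      if (is.null(rec$text)) stop("malformed JSONL at line ", i,
                                  ": missing `text` field", call. = FALSE)
      row <- tibble(doc_id = as.character(rec$id %||% as.character(i)),
                    text = as.character(rec$text))
      if (!is.null(rec$labels) && length(rec$labels)) {
        for (nm in names(rec$labels)) row[[nm]] <- as.character(rec$labels[[nm]])
      }
      row
    })
    docs <- bind_rows(recs)
  }
  if (anyDuplicated(docs$doc_id)) stop("duplicate doc_id in corpus")
  docs
}

#' Write documents as JSONL
#'
#' Inverse of [read_corpus()] for the JSONL format; label columns are
#' written into a `labels` object.
#'
#' @param docs Document tibble (`doc_id`, `text`, label columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(docs, path) {
  label_cols <- setdiff(names(docs), c("doc_id", "text"))
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    rec <- list(id = docs$doc_id[[i]], text = docs$text[[i]])
    if (length(label_cols)) {
      labs <- lapply(label_cols, function(c) docs[[c]][[i]])
      names(labs) <- label_cols
      rec$labels <- labs
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Segment documents into fixed-length contexts
#'
#' Cleans each document's text ([clean_tokens()]) and slices the cleaned
#' token stream into consecutive windows of exactly `window` tokens. A final
#' window shorter than `window` is dropped, because it would represent less
#' context than the others; an exactly full final window is retained unless
#' `drop_final_always = TRUE`. Chunks never span documents, and documents
#' shorter than `window` contribute no contexts (a message reports how
#' many).
#'
#' With `clean_first = FALSE` the raw whitespace tokens are windowed first
#' and cleaning is applied within each window afterwards, so retained chunks
#' may then hold fewer than `window` tokens. This variant exists for
#' sensitivity checks; the default counts windows over content words.
#'
#' @param docs Document tibble from [read_corpus()].
#' @param window Context length in tokens (default 1000; 100 is a common
#'   robustness setting).
#' @param config A [clean_config()].
#' @param clean_first Clean before windowing (default `TRUE`).
#' @param drop_final_always Drop the final window even when exactly full
#'   (default `FALSE`).
#' @return Tibble of class `semdiv_chunks`: `context_id` (1-based,
#'   corpus-wide, increasing in corpus order), `doc_id`, `n_tokens`,
#'   `tokens` (list column), plus the documents' label columns.
#' @export
chunk_documents <- function(docs, window = 1000L, config = clean_config(),
                            clean_first = TRUE, drop_final_always = FALSE) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be a positive integer")
  stopifnot(is.data.frame(docs))
  label_cols <- setdiff(names(docs), c("doc_id", "text"))

  per_doc <- lapply(seq_len(nrow(docs)), function(i) {
    toks <- if (clean_first) {
      clean_tokens(docs$text[[i]], config)
    } else {
      raw <- unlist(strsplit(docs$text[[i]], "\\s+"), use.names = FALSE)
      raw[nzchar(raw)]
    }
    n <- length(toks)
    n_full <- n %/% window
    if (drop_final_always && n_full > 0 && n %% window == 0L) {
      n_full <- n_full - 1L
    }
    if (n_full == 0) return(NULL)
    chunks <- lapply(seq_len(n_full), function(j) {
      w <- toks[((j - 1L) * window + 1L):(j * window)]
      if (!clean_first) w <- clean_tokens(paste(w, collapse = " "), config)
      w
    })
    row <- tibble(doc_id = docs$doc_id[[i]],
                  n_tokens = lengths(chunks),
                  tokens = chunks)
    for (c in label_cols) row[[c]] <- docs[[c]][[i]]
    row
  })
  n_empty <- sum(vapply(per_doc, is.null, logical(1)))
  if (n_empty > 0) {
    message(n_empty, " document(s) shorter than the window contributed no contexts")
  }
  out <- bind_rows(per_doc)
  if (nrow(out) == 0) {
    out <- tibble(doc_id = character(), n_tokens = integer(),
                  tokens = list())
  }
  out <- tibble(context_id = seq_len(nrow(out)), out)
  class(out) <- c("semdiv_chunks", class(out))
  out
}

#' Write the chunk manifest (TSV)
#'
#' One row per retained context: `context_id`, `doc_id`, `n_tokens` and any
#' label columns. Token contents are not written.
#'
#' @param chunks Chunk tibble from [chunk_documents()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_chunk_manifest <- function(chunks, path) {
  readr::write_tsv(select(as_tibble(chunks), -"tokens"), path)
  invisible(path)
}
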