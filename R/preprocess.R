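#' Token-cleaning configuration
#'
#' Bundles the cleaning rules applied to raw text before chunking and
#' counting: lowercasing, removal of non-alphabetic characters, a minimum
#' token length (one-letter words are dropped by default), a stoplist of
#' function words, and an optional surface-form to lemma map.
#'
#' @param lowercase Lowercase tokens before any filtering? Default `TRUE`.
#' @param stoplist Character vector of words to remove. Defaults to the
#'   shipped English function-word list ([default_stoplist()]). Use
#'   `character(0)` to keep everything.
#' @param lemma_map Named character vector mapping surface forms to lemmas
#'   (names = surface, values = lemma), or `NULL` for no lemmatisation.
#'   Applied after character cleaning, before stoplist filtering.
#' @param min_word_len Minimum token length kept. Default 2, i.e. one-letter
#'   words are removed.
#' @param nonalpha One of `"strip"` (default: non-alphabetic characters are
#'   deleted inside tokens, so `cat's` becomes `cats`) or `"split"`
#'   (non-alphabetic characters act as token separators, so `cat's` becomes
#'   `cat` and `s`).
#'
#' @return An object of class `clean_config`.
#' @export
#' @examples
#' cfg <- clean_config(stoplist = c("the"))
#' clean_tokens("The cat's 9 lives!", cfg)
clean_config <- function(lowercase = TRUE,
                         stoplist = default_stoplist(),
                         lemma_map = NULL,
                         min_word_len = 2L,
                         nonalpha = c("strip", "split")) {
  nonalpha <- match.arg(nonalpha)
  if (!is.null(lemma_map)) {
    if (is.data.frame(lemma_map)) {
      lemma_map <- stats::setNames(as.character(lemma_map[[2]]),
                                   as.character(lemma_map[[1]]))
    }
    stopifnot(is.character(lemma_map), !is.null(names(lemma_map)))
  }
  stoplist <- as.character(stoplist)
  if (lowercase) stoplist <- tolower(stoplist)
  structure(
    list(lowercase = lowercase, stoplist = unique(stoplist),
         lemma_map = lemma_map, min_word_len = as.integer(min_word_len),
         nonalpha = nonalpha),
    class = "clean_config"
  )
}

#' Shipped English function-word stoplist
#'
#' A general-purpose list of English function words (articles, prepositions,
#' pronouns, auxiliaries, conjunctions). It is a documented default, not a
#' canonical standard: replace it with your own list via the `stoplist`
#' argument of [clean_config()] or a one-word-per-line file read with
#' [read_stoplist()] when comparability with published norms matters.
#'
#' @return Character vector of lowercase words.
#' @export
default_stoplist <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "semdiv")
  unique(read_stoplist(path))
}

#' Read a stoplist file (one word per line)
#'
#' @param path File path; blank lines and leading/trailing whitespace are
#'   ignored.
#' @return Character vector.
#' @export
read_stoplist <- function(path) {
  if (!file.exists(path)) stop("stoplist file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  x[nzchar(x)]
}

#' Read a lemma map (two-column TSV: surface, lemma)
#'
#' @param path TSV file with two columns and no header: surface form, lemma.
#' @return Named character vector suitable for [clean_config()].
#' @export
read_lemma_map <- function(path) {
  if (!file.exists(path)) stop("lemma map file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, col.names = c("surface", "lemma"),
                          colClasses = "character", quote = "")
  stats::setNames(df$lemma, df$surface)
}

#' Clean raw text into content-word tokens
#'
#' Tokenises on whitespace, removes non-alphabetic characters (by stripping
#' them within tokens or splitting on them, per the config), lowercases,
#' drops tokens shorter than `min_word_len`, applies the lemma map, and then
#' removes stoplist words. The output may be empty.
#'
#' @param text A character string (or vector, concatenated in order).
#' @param config A [clean_config()].
#' @return Character vector of cleaned tokens, in original order.
#' @export
#' @examples
#' clean_tokens("The cat's 9 lives!", clean_config(stoplist = "the"))
clean_tokens <- function(text, config = clean_config()) {
  stopifnot(inherits(config, "clean_config"))
  toks <- unlist(strsplit(paste(text, collapse = " "), "\\s+"), use.names = FALSE)
  if (config$nonalpha == "split") {
    toks <- unlist(strsplit(toks, "[^[:alpha:]]+"), use.names = FALSE)
  } else {
    toks <- gsub("[^[:alpha:]]", "", toks)
  }
  toks <- toks[nzchar(toks)]
  if (config$lowercase) toks <- tolower(toks)
  toks <- toks[nchar(toks) >= config$min_word_len]
  if (!is.null(config$lemma_map)) {
    hit <- toks %in% names(config$lemma_map)
    toks[hit] <- unname(config$lemma_map[toks[hit]])
  }
  if (length(config$stoplist)) toks <- toks[!toks %in% config$stoplist]
  toks
}

#' Build the retained vocabulary from chunked contexts
#'
#' Counts corpus frequency and context frequency (number of distinct
#' contexts containing the word) for every token, then applies the two
#' frequency thresholds. Under the default rule a word is kept only if its
#' total count is at least `min_count` AND it appears in at least
#' `min_contexts` contexts; rare or narrow words are excluded. The literal
#' Boolean alternative (exclude only words failing both thresholds) is
#' available as `rule = "either"`.
#'
#' Columns are ordered by descending total count, ties broken
#' alphabetically, and `index` gives the 1-based column position used by
#' [build_cooc()].
#'
#' @param chunks Chunk tibble from [chunk_documents()].
#' @param min_count Minimum corpus frequency (default 50).
#' @param min_contexts Minimum number of distinct contexts (default 40).
#' @param rule `"both"` (default: keep words meeting both thresholds) or
#'   `"either"` (keep words meeting at least one).
#' @return A tibble of class `semdiv_vocab` with columns `word`, `count`,
#'   `context_count`, `index`, and attributes `min_count`, `min_contexts`,
#'   `rule`.
#' @export
build_vocabulary <- function(chunks, min_count = 50L, min_contexts = 40L,
                             rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (!is.data.frame(chunks) || nrow(chunks) == 0) {
    stop("`chunks` must be a nonempty chunk tibble")
  }
  toks <- chunks$tokens
  total <- table(unlist(toks, use.names = FALSE))
  ctx <- table(unlist(lapply(toks, unique), use.names = FALSE))
  words <- names(total)
  tbl <- tibble(
    word = words,
    count = as.integer(total[words]),
    context_count = as.integer(ctx[words])
  )
  keep <- if (rule == "both") {
    tbl$count >= min_count & tbl$context_count >= min_contexts
  } else {
    tbl$count >= min_count | tbl$context_count >= min_contexts
  }
  out <- tbl[keep, , drop = FALSE]
  out <- out[order(-out$count, out$word), , drop = FALSE]
  out$index <- seq_len(nrow(out))
  attr(out, "min_count") <- as.integer(min_count)
  attr(out, "min_contexts") <- as.integer(min_contexts)
  attr(out, "rule") <- rule
  class(out) <- c("semdiv_vocab", class(out))
  out
}

#' Write a vocabulary to TSV
#'
#' @param vocab A `semdiv_vocab` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_tsv(as_tibble(vocab), path)
  invisible(path)
}
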