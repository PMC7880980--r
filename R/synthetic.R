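#' Specification of a synthetic topic-structured corpus
#'
#' Describes a corpus of documents drawn from `n_topics` topics, each topic
#' with its own word inventory plus a shared pool, and a set of planted
#' words whose topic spread is controlled: "narrow" words confined to one
#' topic, "diverse" words spread over many, and ambiguous words whose
#' occurrences carry a ground-truth meaning label. Such corpora let every
#' pipeline stage — and the interpretation of SemD as topic spread rather
#' than meaning variation — be tested without licensed corpora.
#'
#' @param n_topics Number of topics K.
#' @param docs_per_topic Documents generated per topic (one topic per
#'   document).
#' @param doc_length Background tokens per document (before planted
#'   insertions).
#' @param vocab_per_topic Size of each topic's private word inventory.
#' @param shared_vocab Size of the shared word pool.
#' @param planted List of planted-word descriptions, each a list with
#'   `word` (alphabetic string), `topics` (integer vector, subset of
#'   `1:n_topics`), `rate` (expected occurrences per document of a matching
#'   topic; Poisson), and optionally `meanings`: either a named character
#'   vector mapping topic -> meaning label (meaning keyed by topic), or
#'   `list(mode = "random", labels = c(...))` (meaning drawn per document
#'   independently of topic — identical topic-spread profiles per meaning).
#' @param shared_fraction Probability that a background token comes from the
#'   shared pool rather than the topic inventory (default 0.3).
#' @param seed RNG seed; the same spec yields a byte-identical corpus.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_topics = 5L, docs_per_topic = 12L,
                           doc_length = 240L, vocab_per_topic = 60L,
                           shared_vocab = 40L, planted = list(),
                           shared_fraction = 0.3, seed = 42L) {
  n_topics <- as.integer(n_topics)
  stopifnot(n_topics >= 1, docs_per_topic >= 1, doc_length >= 1,
            vocab_per_topic >= 1, shared_vocab >= 0,
            shared_fraction >= 0, shared_fraction < 1)
  per_topic_rate <- numeric(n_topics)
  for (p in planted) {
    stopifnot(is.character(p$word), grepl("^[a-z]{2,}$", p$word),
              length(p$topics) >= 1, all(p$topics %in% seq_len(n_topics)),
              is.numeric(p$rate), p$rate > 0)
    per_topic_rate[p$topics] <- per_topic_rate[p$topics] + p$rate
    if (!is.null(p$meanings) && !is.list(p$meanings)) {
      stopifnot(!is.null(names(p$meanings)),
                all(names(p$meanings) %in% as.character(p$topics)))
    }
  }
  if (any(per_topic_rate >= doc_length)) {
    stop("infeasible spec: expected planted insertions exceed doc_length")
  }
  structure(
    list(n_topics = n_topics, docs_per_topic = as.integer(docs_per_topic),
         doc_length = as.integer(doc_length),
         vocab_per_topic = as.integer(vocab_per_topic),
         shared_vocab = as.integer(shared_vocab),
         planted = planted, shared_fraction = shared_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# deterministic alphabetic pseudo-word: base-26 index in letters
enc26 <- function(i, width = 3L) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    x <- i[k] - 1L
    s <- ""
    for (d in seq_len(width)) {
      s <- paste0(letters[x %% 26L + 1L], s)
      x <- x %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Generate a synthetic topic-structured corpus
#'
#' Each document is assigned one topic; background tokens are drawn i.i.d.
#' from a Zipf-weighted mixture of the topic's private inventory and the
#' shared pool; each planted word whose spread covers the document's topic
#' is inserted a Poisson(`rate`) number of times (each insertion replaces a
#' background token at a uniform position, so every document is exactly
#' `doc_length` tokens); and ambiguous planted words record the ground-truth
#' meaning of every document's occurrences. Fully reproducible from the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_corpus`: list with `documents`
#'   (tibble `doc_id`, `text`, `domain`), `planted` (tibble `word`,
#'   `topic_spread`, `rate`, `total_insertions`, `ambiguous`), and
#'   `occurrences` (tibble `doc_id`, `word`, `meaning`, `n_insertions` for
#'   every planted word with insertions).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$n_topics
  topic_words <- lapply(seq_len(K), function(t) {
    paste0(letters[t], "q", enc26(seq_len(spec$vocab_per_topic)))
  })
  shared_words <- if (spec$shared_vocab > 0) {
    paste0("zs", enc26(seq_len(spec$shared_vocab)))
  } else character()
  zipf <- function(m) if (m > 0) (1 / seq_len(m)) / sum(1 / seq_len(m)) else numeric()

  with_seed_(spec$seed, {
    docs <- vector("list", K * spec$docs_per_topic)
    occ <- list()
    i <- 0L
    for (t in seq_len(K)) {
      pool <- c(topic_words[[t]], shared_words)
      prob <- c((1 - spec$shared_fraction) * zipf(spec$vocab_per_topic),
                spec$shared_fraction * zipf(spec$shared_vocab))
      prob <- prob / sum(prob)
      for (d in seq_len(spec$docs_per_topic)) {
        i <- i + 1L
        doc_id <- sprintf("t%02d_d%03d", t, d)
        toks <- sample(pool, spec$doc_length, replace = TRUE, prob = prob)
        ins_words <- character()
        for (p in spec$planted) {
          if (!t %in% p$topics) next
          n_ins <- min(rpois(1, p$rate), spec$doc_length %/% 4L)
          meaning <- NA_character_
          if (!is.null(p$meanings)) {
            meaning <- if (is.list(p$meanings)) {
              sample(p$meanings$labels, 1)
            } else {
              unname(p$meanings[[as.character(t)]])
            }
          }
          if (n_ins > 0) {
            ins_words <- c(ins_words, rep(p$word, n_ins))
            occ[[length(occ) + 1L]] <- tibble(
              doc_id = doc_id, word = p$word, meaning = meaning,
              n_insertions = n_ins)
          }
        }
        if (length(ins_words) > 0) {
          # planted occurrences replace background tokens at uniform
          # positions, so every document is exactly doc_length tokens
          pos <- sample.int(spec$doc_length, length(ins_words))
          toks[pos] <- ins_words
        }
        docs[[i]] <- tibble(doc_id = doc_id,
                            text = paste(toks, collapse = " "),
                            domain = sprintf("topic%02d", t))
      }
    }
    occurrences <- if (length(occ)) bind_rows(occ) else {
      tibble(doc_id = character(), word = character(),
             meaning = character(), n_insertions = integer())
    }
    planted_tbl <- bind_rows(lapply(spec$planted, function(p) {
      tibble(word = p$word, topic_spread = length(p$topics), rate = p$rate,
             total_insertions = sum(occurrences$n_insertions[
               occurrences$word == p$word]),
             ambiguous = !is.null(p$meanings))
    }))
    structure(
      list(documents = bind_rows(docs), planted = planted_tbl,
           occurrences = occurrences, spec = spec),
      class = "synthetic_corpus"
    )
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$documents), " documents, ",
      x$spec$n_topics, " topics, ", nrow(x$planted), " planted words\n",
      sep = "")
  invisible(x)
}

#' Read a synthetic-corpus spec from YAML
#'
#' The YAML mirrors the arguments of [synthetic_spec()] plus an optional
#' `pipeline` block (window, min_count, min_contexts, k, scaled, seed) with
#' run settings for the corpus.
#'
#' @param path YAML file.
#' @return List with `spec` (a `synthetic_spec`) and `pipeline` (a list,
#'   possibly empty).
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  planted <- lapply(y$planted %||% list(), function(p) {
    m <- p$meanings
    if (!is.null(m)) {
      m <- if (identical(m, "random")) {
        list(mode = "random", labels = as.character(p$meaning_labels))
      } else {
        stats::setNames(as.character(unlist(m)), names(m))
      }
    }
    list(word = p$word, topics = as.integer(unlist(p$topics)),
         rate = as.numeric(p$rate), meanings = m)
  })
  spec <- synthetic_spec(
    n_topics = y$n_topics %||% 5L,
    docs_per_topic = y$docs_per_topic %||% 12L,
    doc_length = y$doc_length %||% 240L,
    vocab_per_topic = y$vocab_per_topic %||% 60L,
    shared_vocab = y$shared_vocab %||% 40L,
    planted = planted,
    shared_fraction = y$shared_fraction %||% 0.3,
    seed = y$seed %||% 42L
  )
  list(spec = spec, pipeline = y$pipeline %||% list())
}

#' The committed reference spec
#'
#' The canonical synthetic corpus used throughout the package's tests and
#' reproduction script: 5 topics, planted words at topic spreads 1-5 with
#' equal expected total frequency, one topic-keyed ambiguous word (its two
#' meanings live in different topics) and one spread-matched ambiguous word
#' (its two meanings share an identical topic profile).
#'
#' @param seed Optional override of the corpus seed.
#' @return As [read_synthetic_spec()].
#' @export
reference_spec <- function(seed = NULL) {
  path <- system.file("extdata", "reference_spec.yaml", package = "semdiv")
  out <- read_synthetic_spec(path)
  if (!is.null(seed)) out$spec$seed <- as.integer(seed)
  out
}

#' Recovery report: does the pipeline see the planted structure?
#'
#' Joins the planted-word ground truth with a computed SemD table and
#' reports (a) the Spearman correlation between designed topic spread and
#' SemD over the unambiguous planted words, and (b) for each ambiguous
#' planted word, the Calinski-Harabasz separability of its ground-truth
#' meaning labels against the random-label baseline (z = (CH - baseline
#' mean) / baseline sd). Planted words eliminated by the vocabulary
#' thresholds are reported with status `"filtered_out"`, not treated as
#' fatal.
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param space The `semantic_space` built from its documents.
#' @param semd_tbl SemD table ([semdiv_table()]) for that space.
#' @param n_iterations Baseline permutations for the ambiguous-word checks.
#' @param seed Seed for the baselines.
#' @return Object of class `recovery_report`: list with `word_table`
#'   (tibble: word, topic_spread, semd, status), `spearman_rho`, and
#'   `ambiguous` (tibble: word, ch, baseline_mean, baseline_sd, z).
#' @export
ground_truth_report <- function(corpus, space, semd_tbl,
                                n_iterations = 500L, seed = 1L) {
  stopifnot(inherits(corpus, "synthetic_corpus"),
            inherits(space, "semantic_space"))
  planted <- corpus$planted
  if (nrow(planted) == 0) {
    warning("no planted words in corpus; empty report")
    return(structure(list(word_table = tibble(), spearman_rho = NA_real_,
                          ambiguous = tibble()),
                     class = "recovery_report"))
  }
  st <- as_tibble(semd_tbl)
  wt <- planted %>%
    left_join(select(st, "word", "n_contexts", "semd", "status"), by = "word") %>%
    mutate(status = dplyr::coalesce(.data$status, "filtered_out"))
  if (all(wt$status == "filtered_out")) {
    warning("all planted words were eliminated by the vocabulary thresholds")
  }
  div <- filter(wt, !.data$ambiguous, is.finite(.data$semd))
  rho <- if (nrow(div) >= 3 && length(unique(div$topic_spread)) > 1) {
    cor(div$topic_spread, div$semd, method = "spearman")
  } else {
    message("topic-spread/SemD correlation undefined ",
            "(fewer than 3 scored words or no spread variation)")
    NA_real_
  }
  amb_words <- filter(wt, .data$ambiguous, .data$status == "ok")$word
  amb <- bind_rows(lapply(amb_words, function(w) {
    labs <- meaning_labels_for(corpus, space, w)
    if (length(unique(labs)) < 2) {
      return(tibble(word = w, ch = NA_real_, baseline_mean = NA_real_,
                    baseline_sd = NA_real_, z = NA_real_))
    }
    d <- word_context_diagnostic(space, w, labs, fraction = 1.0,
                                 n_iterations = n_iterations, seed = seed)
    tibble(word = w, ch = d$ch_score, baseline_mean = d$baseline_mean,
           baseline_sd = d$baseline_sd,
           z = (d$ch_score - d$baseline_mean) / d$baseline_sd)
  }))
  structure(
    list(word_table = select(wt, "word", "topic_spread", "n_contexts",
                             "semd", "status"),
         spearman_rho = rho, ambiguous = amb),
    class = "recovery_report"
  )
}

# ground-truth meaning label of every context containing `word`, keyed by
# context id (meanings are constant within a document, and chunks never
# span documents)
meaning_labels_for <- function(corpus, space, word) {
  occ <- filter(corpus$occurrences, .data$word == !!word)
  doc_meaning <- stats::setNames(occ$meaning, occ$doc_id)
  rows <- space$word_contexts[[word]]
  ids <- space$context_ids[rows]
  meta <- space$context_meta
  docs <- meta$doc_id[match(ids, meta$context_id)]
  stats::setNames(unname(doc_meaning[docs]), as.character(ids))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n  Spearman rho (topic spread vs SemD): ",
      signif(x$spearman_rho, 4), "\n", sep = "")
  if (nrow(x$ambiguous)) {
    for (i in seq_len(nrow(x$ambiguous))) {
      cat("  ambiguous '", x$ambiguous$word[i], "': CH = ",
          signif(x$ambiguous$ch[i], 4), ", baseline M = ",
          signif(x$ambiguous$baseline_mean[i], 4), " (z = ",
          signif(x$ambiguous$z[i], 3), ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a synthetic corpus to disk (JSONL + ground-truth TSVs)
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus_jsonl(corpus$documents, file.path(dir, "corpus.jsonl"))
  readr::write_tsv(corpus$planted, file.path(dir, "planted.tsv"))
  readr::write_tsv(corpus$occurrences, file.path(dir, "occurrences.tsv"))
  invisible(dir)
}
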