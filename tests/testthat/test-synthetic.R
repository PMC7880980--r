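test_that("the generator honours the spec's arithmetic and labels", {
  spec <- synthetic_spec(n_topics = 5, docs_per_topic = 4, doc_length = 120,
                         vocab_per_topic = 20, shared_vocab = 10, seed = 3)
  corpus <- generate_corpus(spec)
  expect_equal(nrow(corpus$documents), 20)
  expect_equal(sort(unique(corpus$documents$domain)),
               sprintf("topic%02d", 1:5))
  lens <- lengths(strsplit(corpus$documents$text, " "))
  expect_true(all(lens == 120))  # no planted words here
})

test_that("the same seed yields a byte-identical corpus", {
  ref <- reference_spec()
  c1 <- generate_corpus(ref$spec)
  c2 <- generate_corpus(ref$spec)
  expect_identical(c1$documents, c2$documents)
  expect_identical(c1$occurrences, c2$occurrences)
  ref2 <- reference_spec(seed = 777)
  c3 <- generate_corpus(ref2$spec)
  expect_false(identical(c1$documents$text, c3$documents$text))
})

test_that("document lengths match the spec exactly (insertions replace tokens)", {
  ref <- reference_spec()
  corpus <- generate_corpus(ref$spec)
  lens <- lengths(strsplit(corpus$documents$text, " "))
  expect_true(all(lens == ref$spec$doc_length))
})

test_that("planted insertions respect topic spread and meaning keys", {
  ref <- reference_spec()
  corpus <- generate_corpus(ref$spec)
  occ <- corpus$occurrences
  # narrow word never leaves its topic
  expect_true(all(grepl("^t01", occ$doc_id[occ$word == "narrowa"])))
  # topic-keyed meanings are deterministic in the topic
  tk <- occ[occ$word == "twokeyed", ]
  expect_true(all(tk$meaning[grepl("^t01", tk$doc_id)] == "meadow"))
  expect_true(all(tk$meaning[grepl("^t04", tk$doc_id)] == "finance"))
  # spread-matched meanings occur across all topics
  eb <- occ[occ$word == "evenblend", ]
  expect_setequal(unique(eb$meaning), c("sensea", "senseb"))
  expect_gt(length(unique(substr(eb$doc_id, 1, 3))), 3)
  expect_equal(sum(occ$n_insertions),
               sum(corpus$planted$total_insertions))
})

test_that("infeasible and malformed specs are rejected", {
  expect_error(synthetic_spec(planted = list(
    list(word = "flood", topics = 1, rate = 500)), doc_length = 100),
    "infeasible")
  expect_error(synthetic_spec(planted = list(
    list(word = "x9", topics = 1, rate = 1))))
  expect_error(synthetic_spec(planted = list(
    list(word = "okword", topics = 99, rate = 1))))
})

test_that("the recovery report orders planted words by topic spread", {
  ref <- reference_spec()
  corpus <- generate_corpus(ref$spec)
  pl <- ref$pipeline
  space <- suppressMessages(build_semantic_space(
    corpus$documents, window = pl$window, min_count = pl$min_count,
    min_contexts = pl$min_contexts, k = pl$k, seed = pl$seed))
  tbl <- semdiv_table(space)
  rep <- ground_truth_report(corpus, space, tbl, n_iterations = 200, seed = 5)
  expect_gte(rep$spearman_rho, 0.8)
  expect_equal(nrow(rep$word_table), nrow(corpus$planted))
  expect_true(all(rep$word_table$status == "ok"))
})

test_that("planted words killed by thresholds are reported, not fatal", {
  ref <- reference_spec()
  corpus <- generate_corpus(ref$spec)
  pl <- ref$pipeline
  # absurd thresholds eliminate all planted words
  space <- suppressMessages(suppressWarnings(build_semantic_space(
    corpus$documents, window = pl$window, min_count = 500,
    min_contexts = 100, k = 10, seed = pl$seed)))
  tbl <- semdiv_table(space)
  expect_warning(
    rep <- suppressMessages(
      ground_truth_report(corpus, space, tbl, n_iterations = 50, seed = 1)),
    "eliminated")
  expect_true(all(rep$word_table$status == "filtered_out"))
  expect_true(is.na(rep$spearman_rho))
})

test_that("identical spreads leave the spread correlation undefined", {
  spec <- synthetic_spec(
    n_topics = 3, docs_per_topic = 8, doc_length = 150,
    vocab_per_topic = 25, shared_vocab = 10, seed = 5,
    planted = list(list(word = "flata", topics = 1:3, rate = 1),
                   list(word = "flatb", topics = 1:3, rate = 1)))
  corpus <- generate_corpus(spec)
  space <- suppressMessages(build_semantic_space(
    corpus$documents, window = 50, min_count = 5, min_contexts = 3,
    k = 20, seed = 1))
  tbl <- semdiv_table(space)
  expect_message(
    rep <- ground_truth_report(corpus, space, tbl, n_iterations = 50, seed = 1),
    "undefined")
  expect_true(is.na(rep$spearman_rho))
})

test_that("a word spanning five topics outranks a one-topic word across replicates", {
  spec_for <- function(seed) synthetic_spec(
    n_topics = 5, docs_per_topic = 8, doc_length = 150,
    vocab_per_topic = 30, shared_vocab = 20, seed = seed,
    planted = list(list(word = "narrowone", topics = 1, rate = 2.5),
                   list(word = "widefive", topics = 1:5, rate = 0.5)))
  wins <- 0L
  for (r in 1:20) {
    corpus <- generate_corpus(spec_for(1000 + r))
    space <- suppressMessages(suppressWarnings(build_semantic_space(
      corpus$documents, window = 50, min_count = 5, min_contexts = 3,
      k = 30, seed = 1)))
    tbl <- semdiv_table(space, c("narrowone", "widefive"))
    if (all(tbl$status == "ok") && tbl$semd[2] > tbl$semd[1]) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("synthetic corpora round-trip to JSONL and ground-truth TSVs", {
  spec <- synthetic_spec(n_topics = 2, docs_per_topic = 3, doc_length = 60,
                         vocab_per_topic = 15, shared_vocab = 5, seed = 1,
                         planted = list(list(word = "markedword",
                                             topics = 1:2, rate = 1)))
  corpus <- generate_corpus(spec)
  dir <- withr::local_tempdir()
  write_synthetic_corpus(corpus, dir)
  docs <- read_corpus(file.path(dir, "corpus.jsonl"), format = "jsonl")
  expect_equal(docs$text, corpus$documents$text)
  expect_equal(docs$domain, corpus$documents$domain)
  planted <- readr::read_tsv(file.path(dir, "planted.tsv"),
                             show_col_types = FALSE)
  expect_equal(planted$word, corpus$planted$word)
})

test_that("yaml specs parse into the same corpus as programmatic ones", {
  ref <- reference_spec()
  expect_s3_class(ref$spec, "synthetic_spec")
  expect_equal(ref$pipeline$window, 100)
  expect_equal(ref$spec$n_topics, 5)
  amb <- Filter(function(p) !is.null(p$meanings), ref$spec$planted)
  expect_equal(length(amb), 2)
})
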