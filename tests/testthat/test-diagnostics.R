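test_that("the variance-ratio score matches a hand-computed toy case", {
  # 6 points, 2 labels, 1-d: groups {0,1,2} and {10,11,12}
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  labs <- rep(c("a", "b"), each = 3)
  # grand mean 6; between = 3*(1-6)^2 + 3*(11-6)^2 = 150; within = 2+2 = 4
  expect_equal(calinski_harabasz(x, labs), (150 / 1) / (4 / 4),
               tolerance = 1e-12)
})

test_that("the score agrees with the brute-force trace ratio on random sets", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    k <- sample(2:6, 1)
    g <- sample(2:4, 1)
    x <- matrix(rnorm(n * k), n, k)
    labs <- sample(letters[1:g], n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    expect_equal(calinski_harabasz(x, labs), oracle_ch(x, labs),
                 tolerance = 1e-9)
  }
})

test_that("the score is invariant to translation/rotation and to uniform scaling", {
  set.seed(8)
  x <- matrix(rnorm(40 * 3), 40, 3)
  labs <- rep(c("a", "b", "c", "d"), 10)
  ch0 <- calinski_harabasz(x, labs)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(calinski_harabasz(sweep(x, 2, c(5, -2, 7), `+`), labs), ch0,
               tolerance = 1e-9)
  expect_equal(calinski_harabasz(x %*% q, labs), ch0, tolerance = 1e-9)
  expect_equal(calinski_harabasz(3.7 * x, labs), ch0, tolerance = 1e-9)
})

test_that("the score grows with separation of planted clusters", {
  set.seed(12)
  base <- matrix(rnorm(60 * 2, sd = 0.3), 60, 2)
  labs <- rep(c("a", "b"), each = 30)
  scores <- vapply(c(1, 3, 9), function(sep) {
    x <- base
    x[labs == "b", 1] <- x[labs == "b", 1] + sep
    calinski_harabasz(x, labs)
  }, numeric(1))
  expect_gt(scores[1], 1)
  expect_true(all(diff(scores) > 0))
})

test_that("degenerate labellings are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(calinski_harabasz(x, rep("a", 10)), "2 distinct labels")
  perfect <- rbind(matrix(0, 3, 2), matrix(1, 3, 2))
  expect_error(calinski_harabasz(perfect, rep(c("a", "b"), each = 3)),
               "degenerate")
  expect_error(calinski_harabasz(x, c("a", "b")), "one entry per row")
})

test_that("the permutation baseline is seeded, reproducible, near 1", {
  set.seed(4)
  x <- matrix(rnorm(400 * 5), 400, 5)
  x[1:200, 1] <- x[1:200, 1] + 2  # structure, which permutation must erase
  labs <- rep(c("a", "b"), each = 200)
  b1 <- random_label_baseline(x, labs, n_iterations = 200, seed = 99)
  b2 <- random_label_baseline(x, labs, n_iterations = 200, seed = 99)
  expect_identical(b1, b2)
  expect_lt(abs(b1$mean - 1), 0.1)
  b3 <- random_label_baseline(x, labs, n_iterations = 200, seed = 100)
  expect_false(identical(b1$mean, b3$mean))
  expect_warning(b4 <- random_label_baseline(x, labs, n_iterations = 1,
                                             seed = 1), "sd undefined")
  expect_true(is.na(b4$sd))
})

test_that("word diagnostics separate topic-keyed meanings but not random labels", {
  set.seed(30)
  # two orthogonal tight clusters of contexts for one word
  v <- rbind(
    matrix(rep(c(5, 0, 0), 12), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 5, 0), 12), ncol = 3, byrow = TRUE)
  ) + matrix(rnorm(72, sd = 0.3), 24, 3)
  sp <- make_raw_space(v, list(amb = 1:24))
  truth <- stats::setNames(rep(c("animal", "tool"), each = 12),
                           as.character(1:24))
  d <- word_context_diagnostic(sp, "amb", truth, fraction = 1.0,
                               n_iterations = 300, seed = 3)
  expect_gt(d$ch_score, d$baseline_mean + 3 * d$baseline_sd)
  expect_equal(d$n_points, 24)

  rand <- stats::setNames(sample(c("animal", "tool"), 24, replace = TRUE),
                          as.character(1:24))
  d2 <- word_context_diagnostic(sp, "amb", rand, fraction = 1.0,
                                n_iterations = 300, seed = 3)
  expect_lt(abs(d2$ch_score - d2$baseline_mean), 3 * d2$baseline_sd)
})

test_that("the context-sampling fraction is honoured and seeded", {
  v <- matrix(rnorm(60), 20, 3)
  sp <- make_raw_space(v, list(w = 1:20))
  truth <- stats::setNames(rep(c("x", "y"), 10), as.character(1:20))
  d_half <- word_context_diagnostic(sp, "w", truth, fraction = 0.5,
                                    n_iterations = 50, seed = 5)
  expect_equal(d_half$n_points, 10)
  d_half2 <- word_context_diagnostic(sp, "w", truth, fraction = 0.5,
                                     n_iterations = 50, seed = 5)
  expect_equal(tidy(d_half), tidy(d_half2))
  d_all <- word_context_diagnostic(sp, "w", truth, fraction = 1.0,
                                   n_iterations = 50, seed = 5)
  expect_equal(d_all$n_points, 20)
  expect_error(word_context_diagnostic(sp, "w", truth[1:3], fraction = 1),
               "no label")
  one <- stats::setNames(rep("x", 20), as.character(1:20))
  expect_error(word_context_diagnostic(sp, "w", one, fraction = 1),
               "fewer than 2 distinct labels")
})

test_that("corpus-level diagnostics recover planted topic structure", {
  ref <- reference_spec()
  corpus <- generate_corpus(ref$spec)
  pl <- ref$pipeline
  space <- suppressMessages(build_semantic_space(
    corpus$documents, window = pl$window, min_count = pl$min_count,
    min_contexts = pl$min_contexts, k = pl$k, seed = pl$seed))
  d <- corpus_label_diagnostic(space, "domain", n_iterations = 300, seed = 11)
  expect_gt(d$ch_score, 10 * d$baseline_mean)
  expect_equal(d$n_labels, 5)
  # permuting the metadata labels kills the structure
  sp2 <- space
  set.seed(71)
  sp2$context_meta$domain <- sample(space$context_meta$domain)
  d2 <- corpus_label_diagnostic(sp2, "domain", n_iterations = 300, seed = 11)
  expect_lt(abs(d2$ch_score - 1), 0.5)
  expect_error(corpus_label_diagnostic(space, "nosuchdim"), "no metadata")
})

test_that("a structureless label split scores near its baseline", {
  set.seed(60)
  v <- matrix(rnorm(80 * 4), 80, 4)  # single undifferentiated cloud
  sp <- make_raw_space(v, list(w = 1:80),
                       meta = tibble::tibble(context_id = 1:80,
                                             doc_id = sprintf("d%02d", 1:80),
                                             half = rep(c("a", "b"), 40)))
  d <- corpus_label_diagnostic(sp, "half", n_iterations = 300, seed = 2)
  expect_lt(abs(d$ch_score - d$baseline_mean), 3 * d$baseline_sd)
})

test_that("t-SNE output has the contract shape and is seed-deterministic", {
  set.seed(77)
  x <- matrix(rnorm(30 * 5), 30, 5)
  labs <- rep(c("a", "b", "c"), 10)
  e1 <- embed_2d(x, labs, perplexity = 8, seed = 4, n_iter = 150)
  expect_equal(nrow(e1), 30)
  expect_named(e1, c("dim1", "dim2", "label"))
  e2 <- embed_2d(x, labs, perplexity = 8, seed = 4, n_iter = 150)
  expect_identical(e1, e2)
  expect_error(embed_2d(x, labs, perplexity = 30), "perplexity")
  expect_error(embed_2d(x[1:4, ]), "at least 5")
  expect_s3_class(autoplot(e1), "ggplot")
})

test_that("t-SNE keeps two orthogonal planted clusters apart", {
  set.seed(13)
  x <- rbind(matrix(rnorm(20 * 6, mean = 0), 20, 6),
             matrix(rnorm(20 * 6, mean = 6), 20, 6))
  labs <- rep(c("p", "q"), each = 20)
  e <- embed_2d(x, labs, perplexity = 10, seed = 2, n_iter = 300)
  y <- as.matrix(e[, c("dim1", "dim2")])
  # mean silhouette of the true labels is positive in the embedding
  d <- as.matrix(dist(y))
  sil <- vapply(seq_len(40), function(i) {
    own <- labs == labs[i]
    a <- mean(d[i, own & seq_len(40) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("diagnostic reports serialise to JSON", {
  x <- matrix(rnorm(40), 20, 2)
  labs <- rep(c("a", "b"), 10)
  d <- word_context_diagnostic(
    make_raw_space(x, list(w = 1:20)), "w",
    stats::setNames(labs, as.character(1:20)), fraction = 1,
    n_iterations = 20, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_diagnostic(d, f)
  j <- jsonlite::fromJSON(f)
  expect_equal(j$ch, d$ch_score)
  expect_equal(j$iterations, 20)
})
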