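test_that("prefix counts match hand counts and fold case", {
  lm <- build_language_model("THE THE CAT", smoothing_floor = 0)
  expect_equal(prefix_count(lm, "T"), 2L)
  expect_equal(prefix_count(lm, "TH"), 2L)
  expect_equal(prefix_count(lm, "C"), 1L)
  expect_equal(prefix_count(lm, ""), 3L)

  lower <- build_language_model("the", smoothing_floor = 0)
  upper <- build_language_model("THE", smoothing_floor = 0)
  for (p in c("T", "TH", "THE"))
    expect_identical(prefix_count(lower, p), prefix_count(upper, p))
})

test_that("degenerate corpora and vocabularies error", {
  expect_error(build_language_model(""), "empty corpus")
  expect_error(suppressWarnings(build_language_model("...!?")), "empty corpus")
  expect_error(build_language_model("CAT", vocabulary = c("A", "A", "_")),
               "duplicate")
})

test_that("transition probabilities follow the count ratio with a floor", {
  lm0 <- build_language_model("THE THE CAT", smoothing_floor = 0)
  p <- transition_probabilities(lm0, "")
  expect_equal(p[["T"]], 2 / 3)
  expect_equal(p[["C"]], 1 / 3)
  expect_equal(transition_probabilities(lm0, "T")[["H"]], 1)

  fl <- 0.05
  lmf <- build_language_model("THE THE CAT", smoothing_floor = fl)
  pf <- transition_probabilities(lmf, "")
  nV <- length(lmf$vocabulary)
  expect_equal(pf[["T"]], 2 / 3 * (1 - fl) + fl / nV)
  expect_equal(pf[["C"]], 1 / 3 * (1 - fl) + fl / nV)
  expect_true(all(pf >= fl / nV - 1e-12))

  expect_message(pq <- transition_probabilities(lmf, "QQQ"), "unseen")
  expect_equal(unname(pq), rep(1 / nV, nV))
})

test_that("transition distributions match a brute-force corpus scan", {
  vocab <- c(LETTERS, as.character(1:9), "_")
  set.seed(101)
  for (rep in 1:5) {
    words <- replicate(200, paste(sample(LETTERS[1:6], sample(1:5, 1),
                                         replace = TRUE), collapse = ""))
    lm <- build_language_model(paste(words, collapse = " "),
                               smoothing_floor = 0)
    for (h in c("", "A", "AB", "BA", sample(words, 3))) {
      got <- suppressMessages(transition_probabilities(lm, h))
      want <- lm_oracle_prob(words, h, vocab)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("random-history distributions are normalized", {
  set.seed(202)
  words <- replicate(300, paste(sample(LETTERS[1:8], sample(1:6, 1),
                                       replace = TRUE), collapse = ""))
  lm <- build_language_model(paste(words, collapse = " "))
  hists <- c("", replicate(1000, paste(sample(LETTERS[1:8], sample(1:4, 1),
                                              replace = TRUE),
                                       collapse = "")))
  sums <- vapply(hists, function(h)
    sum(suppressMessages(transition_probabilities(lm, h))), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("adding a word never lowers its first character's probability", {
  set.seed(303)
  for (rep in 1:10) {
    words <- replicate(50, paste(sample(LETTERS[1:5], sample(1:4, 1),
                                        replace = TRUE), collapse = ""))
    extra <- paste(sample(LETTERS[1:5], 3, replace = TRUE), collapse = "")
    lm1 <- build_language_model(paste(words, collapse = " "),
                                smoothing_floor = 0)
    lm2 <- build_language_model(paste(c(words, extra), collapse = " "),
                                smoothing_floor = 0)
    ch <- substr(extra, 1, 1)
    expect_gte(transition_probabilities(lm2, "")[[ch]],
               transition_probabilities(lm1, "")[[ch]])
  }
})

test_that("non-vocabulary characters act as separators, with a warning", {
  expect_warning(lm <- build_language_model("don't stop"), "dropped")
  # the apostrophe split DON'T into DON + T
  expect_equal(prefix_count(lm, "DON"), 1L)
  expect_equal(prefix_count(lm, "T"), 1L)
})

test_that("language model round-trips through its file format", {
  lm <- build_language_model("THE CAT SAT ON THE MAT",
                             smoothing_floor = 0.03)
  path <- withr::local_tempfile(fileext = ".lm")
  write_language_model(lm, path)
  back <- read_language_model(path)
  expect_identical(back$vocabulary, lm$vocabulary)
  expect_identical(back$smoothing_floor, lm$smoothing_floor)
  expect_identical(back$n_words, lm$n_words)
  for (p in ls(lm$prefix_counts))
    expect_identical(get(p, back$prefix_counts), get(p, lm$prefix_counts))
  expect_equal(transition_probabilities(back, "TH"),
               transition_probabilities(lm, "TH"))
})

test_that("word fragments condition after separators", {
  expect_equal(word_fragment("THE_CA"), "CA")
  expect_equal(word_fragment("THE_"), "")
  expect_equal(word_fragment("CA"), "CA")
  lm <- build_language_model("THE THE CAT", smoothing_floor = 0)
  expect_equal(transition_probabilities(lm, word_fragment("THE_"))[["T"]],
               2 / 3)
})
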