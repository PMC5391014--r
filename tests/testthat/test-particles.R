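test_that("particles initialize with empty histories and uniform weights", {
  ps <- initialize_particles(4)
  expect_equal(particle_weights(ps), rep(0.25, 4))
  expect_true(all(ps$history == ""))
  expect_equal(particle_weights(initialize_particles(1)), 1)
  expect_error(initialize_particles(0), "positive")

  a <- initialize_particles(50, seed = 7)
  lm <- uniform_language_model()
  a <- propose_next_character(a, lm)
  b <- initialize_particles(50, seed = 7)
  b <- propose_next_character(b, lm)
  expect_identical(a$history, b$history)
})

test_that("proposals follow the language model's transition distribution", {
  # degenerate model: only 'A' has support
  lm1 <- build_language_model("A A A", smoothing_floor = 0)
  ps <- initialize_particles(200, seed = 1)
  ps <- propose_next_character(ps, lm1)
  expect_true(all(ps$history == "A"))

  # history 'T' under THE THE CAT forces 'H'
  lm2 <- build_language_model("THE THE CAT", smoothing_floor = 0)
  ps2 <- initialize_particles(100, seed = 2)
  ps2$history <- rep("T", 100)
  ps2 <- propose_next_character(ps2, lm2)
  expect_true(all(ps2$history == "TH"))

  # uniform model: appended fractions within 3 sigma of 1/36
  psu <- initialize_particles(10000, seed = 3)
  psu <- propose_next_character(psu, uniform_language_model())
  frac <- table(factor(psu$history, levels = grid_layout()$characters)) / 10000
  p0 <- 1 / 36
  tol <- 3 * sqrt(p0 * (1 - p0) / 10000)
  expect_true(all(abs(frac - p0) < tol))
})

test_that("weight updates apply the Gaussian likelihood ratio", {
  g <- grid_layout()
  sm <- score_model(2, 1, 0, 1)

  # uninformative likelihood leaves weights unchanged
  sm_flat <- score_model(1, 1, 1, 1)
  ps <- initialize_particles(10, seed = 4)
  ps <- propose_next_character(ps, uniform_language_model())
  w0 <- particle_weights(ps)
  ps2 <- update_weights(ps, 3, 0.7, sm_flat, g)
  expect_equal(particle_weights(ps2), w0)

  # 'A' (row 1) vs 'G' (row 2): flash row 1 at score mu_a -> ratio e^2
  ps <- initialize_particles(2)
  ps$history <- c("A", "G")
  ps <- update_weights(ps, 1, 2, sm, g)
  w <- particle_weights(ps)
  expect_equal(w[1] / w[2], exp(2))

  # flash a group containing both hypotheses: relative weights unchanged
  ps <- initialize_particles(2)
  ps$history <- c("A", "G")         # both in column 1 (group 7)
  ps$log_weight <- log(c(0.3, 0.7))
  ps <- update_weights(ps, 7, 1.3, sm, g)
  expect_equal(particle_weights(ps), c(0.3, 0.7))

  expect_error(update_weights(initialize_particles(2), 1, 0, sm, g),
               "empty histories")
  expect_error(update_weights(ps, 13, 0, sm, g), "out of range")
})

test_that("weights stay normalized through long update chains", {
  g <- grid_layout()
  sm <- score_model(1, 1, 0, 1)
  set.seed(5)
  ps <- initialize_particles(300, seed = 5)
  ps <- propose_next_character(ps, uniform_language_model())
  for (i in 1:120) {
    ps <- update_weights(ps, sample.int(12, 1), rnorm(1), sm, g)
    expect_equal(sum(particle_weights(ps)), 1, tolerance = 1e-9)
    expect_equal(ps$P, 300)
  }
})

test_that("character posterior sums weights by final character", {
  g <- grid_layout()
  ps <- initialize_particles(2)
  ps$history <- c("THA", "THB")
  ps$log_weight <- log(c(0.6, 0.4))
  post <- character_posterior(ps, g)
  expect_equal(post[["A"]], 0.6)
  expect_equal(post[["B"]], 0.4)
  expect_equal(sum(post), 1)

  ps$history <- c("Q", "Q")
  expect_equal(character_posterior(ps, g)[["Q"]], 1)

  ps$log_weight <- c(0, 0)  # unnormalized equal weights
  ps$history <- c("A", "B")
  expect_equal(character_posterior(ps, g)[["A"]], 0.5)
})

test_that("systematic resampling has the promised multiplicities", {
  # a single massive weight takes over the population
  ps <- initialize_particles(20, seed = 6)
  ps$history <- c("Z", rep("A", 19))
  ps$log_weight <- c(0, rep(-1e6, 19))
  ps <- resample(ps)
  expect_true(all(ps$history == "Z"))
  expect_equal(particle_weights(ps), rep(1 / 20, 20))

  # uniform weights: every particle survives exactly once
  ps <- initialize_particles(50, seed = 7)
  ps$history <- as.character(seq_len(50))
  ps <- resample(ps)
  expect_setequal(ps$history, as.character(seq_len(50)))

  # weights (0.7, 0.3) at P = 10000: survivor fractions exact
  ps <- initialize_particles(10000, seed = 8)
  ps$history <- rep(c("A", "B"), c(1, 9999))
  ps$log_weight <- log(c(0.7, rep(0.3 / 9999, 9999)))
  ps <- resample(ps)
  expect_equal(sum(ps$history == "A"), 7000)
})

test_that("particle posterior matches exhaustive Bayes on a tiny grid", {
  g <- tiny_grid()
  lm <- build_language_model("AB AB CA B", vocabulary = g$characters,
                             smoothing_floor = 0.1)
  sm <- score_model(1.5, 1, 0, 1)
  # simulate flashes for hidden string "AB_" (ends the in-corpus word AB,
  # exercising the separator branch): 2 sequences per character
  set.seed(9)
  blocks <- lapply(c("A", "B", "_"), function(tch) {
    sched <- c(sample.int(4), sample.int(4))
    hit <- vapply(sched, function(gr) tch %in% g$groups[[gr]], logical(1))
    data.frame(group = sched,
               score = rnorm(8, ifelse(hit, sm$mu_target, sm$mu_nontarget)))
  })
  want <- enumerate_string_posterior(lm, g, blocks, sm)
  got <- pf_string_posterior(lm, g, blocks, sm, P = 50000, seed = 10)
  expect_lt(total_variation(got, want), 0.01)
})

test_that("with a uniform model the posterior matches naive Bayes", {
  g <- grid_layout()
  sm <- score_model(1, 1, 0, 1)
  set.seed(11)
  sched <- c(sample.int(12), sample.int(12))
  target <- "M"
  hit <- vapply(sched, function(gr) target %in% g$groups[[gr]], logical(1))
  scores <- rnorm(24, ifelse(hit, 1, 0))

  # closed form: per-character product of flash likelihoods
  loglik <- vapply(g$characters, function(ch) {
    ing <- vapply(sched, function(gr) ch %in% g$groups[[gr]], logical(1))
    sum(dnorm(scores, ifelse(ing, sm$mu_target, sm$mu_nontarget),
              log = TRUE))
  }, numeric(1))
  want <- exp(loglik - max(loglik)); want <- want / sum(want)

  ps <- initialize_particles(30000, seed = 12)
  ps <- propose_next_character(ps, uniform_language_model())
  for (i in seq_along(sched))
    ps <- update_weights(ps, sched[i], scores[i], sm, g)
  got <- character_posterior(ps, g)
  expect_lt(sum(abs(got - want)) / 2, 0.02)
})
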