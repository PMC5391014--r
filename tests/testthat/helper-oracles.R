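# Shared fixtures and independent oracles for the test suite.

# -- tiny 2x2 grid whose 4th cell is the word separator ----------------------
tiny_grid <- function() {
  grid_layout(characters = c("A", "B", "C", "_"), n_rows = 2L, n_cols = 2L)
}

# -- brute-force language-model oracle: scan the word list directly ---------
lm_oracle_prob <- function(words, history, vocabulary, separator = "_",
                           floor = 0) {
  denom <- sum(startsWith(words, history))
  nV <- length(vocabulary)
  if (denom == 0) return(stats::setNames(rep(1 / nV, nV), vocabulary))
  raw <- vapply(vocabulary, function(v) {
    if (v == separator) sum(words == history) / denom
    else sum(startsWith(words, paste0(history, v))) / denom
  }, numeric(1))
  p <- (1 - floor) * raw + floor / nV
  p / sum(p)
}

# -- brute-force stepwise-OLS oracle: naive lm() per candidate ---------------
swlda_oracle <- function(x, y, p_enter = 0.10, p_remove = 0.15,
                         max_features = ncol(x)) {
  y <- as.numeric(y)
  included <- integer(0)
  candidate_p <- function(j) {
    d <- as.data.frame(x[, c(included, j), drop = FALSE])
    names(d) <- c(if (length(included)) paste0("inc", seq_along(included)),
                  "cand")
    fit <- stats::lm(y ~ ., data = d)
    cf <- summary(fit)$coefficients
    if (!"cand" %in% rownames(cf)) return(NA_real_)
    cf["cand", 4]
  }
  included_p <- function() {
    d <- as.data.frame(x[, included, drop = FALSE])
    names(d) <- paste0("inc", seq_along(included))
    cf <- summary(stats::lm(y ~ ., data = d))$coefficients
    vapply(seq_along(included), function(i) {
      nm <- paste0("inc", i)
      if (nm %in% rownames(cf)) cf[nm, 4] else 1
    }, numeric(1))
  }
  repeat {
    changed <- FALSE
    if (length(included) < max_features) {
      cand <- setdiff(seq_len(ncol(x)), included)
      if (length(cand)) {
        pv <- vapply(cand, candidate_p, numeric(1))
        if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
          included <- c(included, cand[which(pv == min(pv, na.rm = TRUE))[1]])
          changed <- TRUE
        }
      }
    }
    while (length(included) > 0) {
      pv <- included_p()
      if (max(pv) <= p_remove) break
      included <- included[-which(pv == max(pv))[1]]
      changed <- TRUE
    }
    if (!changed || length(included) >= max_features) break
  }
  included
}

# -- exhaustive string-posterior oracle on a small grid ----------------------
# Enumerates every string of the given length over the grid characters;
# prior from the language model's transition probabilities (conditioning on
# the word fragment, resetting at the separator), likelihood the product of
# per-flash Gaussian densities. Returns the normalized posterior named by
# string.
enumerate_string_posterior <- function(model, grid, flash_blocks, sm) {
  chars <- grid$characters
  len <- length(flash_blocks)
  strings <- do.call(expand.grid,
                     c(rep(list(chars), len),
                       list(stringsAsFactors = FALSE)))
  logpost <- apply(strings, 1, function(s) {
    lp <- 0
    frag <- ""
    for (t in seq_len(len)) {
      p <- transition_probabilities(model, frag)
      lp <- lp + log(p[[s[t]]])
      frag <- if (s[t] == model$separator) "" else paste0(frag, s[t])
      blk <- flash_blocks[[t]]
      for (i in seq_len(nrow(blk))) {
        hit <- s[t] %in% grid$groups[[blk$group[i]]]
        lp <- lp + stats::dnorm(
          blk$score[i],
          if (hit) sm$mu_target else sm$mu_nontarget,
          sqrt(if (hit) sm$var_target else sm$var_nontarget), log = TRUE)
      }
    }
    lp
  })
  w <- exp(logpost - max(logpost))
  stats::setNames(w / sum(w),
                  apply(strings, 1, paste, collapse = ""))
}

# -- particle-filter string posterior (no resampling, SIS form) --------------
pf_string_posterior <- function(model, grid, flash_blocks, sm, P, seed) {
  ps <- initialize_particles(P, seed = seed)
  for (t in seq_along(flash_blocks)) {
    ps <- propose_next_character(ps, model)
    blk <- flash_blocks[[t]]
    for (i in seq_len(nrow(blk)))
      ps <- update_weights(ps, blk$group[i], blk$score[i], sm, grid)
  }
  w <- particle_weights(ps)
  tapply(w, ps$history, sum)
}

total_variation <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  sum(abs(pv - qv)) / 2
}

# -- simulated decode run used by several mechanism tests --------------------
decode_accuracy_run <- function(text, separation, seed, model,
                                threshold = 0.95, P = 400,
                                n_sequences_max = 10L) {
  cfg <- simulation_config(
    text, score_model = score_model(separation, 1, 0, 1),
    n_sequences_max = n_sequences_max, seed = seed)
  st <- simulate_session(cfg)
  dc <- decoder_config(threshold = threshold, P = P, seed = seed + 1000L)
  res <- decode_sequence(st, model, score_model(separation, 1, 0, 1),
                         grid_layout(), dc)
  list(accuracy = accuracy(res$output, text),
       mean_flashes = mean(res$flash_counts),
       result = res)
}

# -- memoized default-corpus language model (punctuation warnings silenced) --
default_lm <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- suppressWarnings(
        build_language_model(read_corpus(default_corpus_path())))
    m
  }
})
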