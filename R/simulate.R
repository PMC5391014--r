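#' Simulation configuration
#'
#' Describes a synthetic spelling session: the hidden target text, the
#' generating Gaussian score model, the stimulus timing, the grid, the
#' number of full flash sequences available per character, and the seed.
#'
#' The default score model, `N(1.25, 1)` for target flashes versus
#' `N(0, 1)` for non-target flashes, is a calibration chosen so that decoded
#' selection rates and accuracies land in the range reported for able-bodied
#' online spelling; it is a package default, not a measured quantity.
#'
#' @param target_text string over the grid characters (use `"_"` for
#'   spaces).
#' @param score_model generating [score_model()].
#' @param timing a [timing_model()].
#' @param grid a [grid_layout()].
#' @param n_sequences_max full 12-flash sequences generated per character
#'   (default 10, matching a 120-flash cap).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(target_text,
                              score_model = pfspeller::score_model(1.25, 1, 0, 1),
                              timing = timing_model(),
                              grid = grid_layout(),
                              n_sequences_max = 10L,
                              seed = 1L) {
  chars <- strsplit(target_text, "", fixed = TRUE)[[1]]
  if (!length(chars)) stop("target_text must be non-empty")
  bad <- setdiff(chars, grid$characters)
  if (length(bad))
    stop("target characters absent from grid: ", paste(bad, collapse = " "))
  stopifnot(n_sequences_max >= 1)
  structure(
    list(target_text = target_text, score_model = score_model,
         timing = timing, grid = grid,
         n_sequences_max = as.integer(n_sequences_max),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a spelling session's score stream
#'
#' For each character of the hidden target text, generates a randomized
#' row/column flash schedule of `n_sequences_max` full sequences and draws
#' one stimulus score per flash: from the target Gaussian when the flashed
#' group contains the target character, from the non-target Gaussian
#' otherwise. Scores are conditionally independent across flashes given the
#' target, mirroring the factorized decoding likelihood. Timestamps follow
#' the timing model.
#'
#' @param config a [simulation_config()].
#' @return a `score_stream`: data frame with columns `character_index`,
#'   `flash_index`, `group`, `score`, `timestamp_ms`, plus attributes
#'   `target` (the hidden text) and `grid`.
#' @examples
#' st <- simulate_session(simulation_config("HI", seed = 7))
#' head(st)
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  grid <- config$grid
  sm <- config$score_model
  chars <- strsplit(config$target_text, "", fixed = TRUE)[[1]]
  n_per_char <- config$n_sequences_max * grid$n_groups
  blocks <- vector("list", length(chars))
  t0 <- 0
  for (k in seq_along(chars)) {
    sched <- unlist(lapply(seq_len(config$n_sequences_max),
                           function(i) sample.int(grid$n_groups)))
    is_target <- vapply(sched, function(g) chars[k] %in% grid$groups[[g]],
                        logical(1))
    score <- ifelse(
      is_target,
      stats::rnorm(n_per_char, sm$mu_target, sqrt(sm$var_target)),
      stats::rnorm(n_per_char, sm$mu_nontarget, sqrt(sm$var_nontarget)))
    ts <- t0 + (seq_len(n_per_char) - 1) * config$timing$soa_ms
    t0 <- ts[n_per_char] + config$timing$soa_ms +
      config$timing$inter_character_pause_ms
    blocks[[k]] <- data.frame(
      character_index = k, flash_index = seq_len(n_per_char),
      group = sched, score = score, timestamp_ms = ts)
  }
  stream <- do.call(rbind, blocks)
  attr(stream, "target") <- config$target_text
  attr(stream, "grid") <- grid
  class(stream) <- c("score_stream", "data.frame")
  stream
}

#' Simulate labeled epoch features consistent with given weights
#'
#' Generates, for each flash of a simulated session, a feature vector whose
#' projection through `weights` reproduces the configured score
#' distributions: the class mean is injected along the weight direction and
#' isotropic Gaussian noise is added, scaled so that
#' `score_epoch(epoch, weights)` is distributed `N(mu_class, var_class)`.
#' This closes the loop for training-pipeline tests: SWLDA refitting and
#' score-model fitting can be exercised end to end without EEG data.
#'
#' @param config a [simulation_config()]; its score model supplies the
#'   target/non-target score distributions.
#' @param weights a [fit_swlda()]-style `feature_weights` object with at
#'   least one selected feature.
#' @return list of class `epoch_stream`: `features` (epochs x
#'   `weights$n_features` matrix), `label` (logical), `group`,
#'   `character_index`, `flash_index`, `target` (the hidden text).
#' @export
simulate_epoch_features <- function(config, weights) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(weights, "feature_weights"))
  if (!length(weights$selected) ||
      sum(weights$coefficients^2) == 0)
    stop("weights must select at least one feature with non-zero norm")
  set.seed(config$seed)
  grid <- config$grid
  sm <- config$score_model
  chars <- strsplit(config$target_text, "", fixed = TRUE)[[1]]
  n_per_char <- config$n_sequences_max * grid$n_groups
  n_total <- n_per_char * length(chars)
  p <- weights$n_features
  wvec <- numeric(p)
  wvec[weights$selected] <- weights$coefficients
  wnorm2 <- sum(wvec^2)

  group <- integer(n_total); label <- logical(n_total)
  character_index <- rep(seq_along(chars), each = n_per_char)
  flash_index <- rep(seq_len(n_per_char), length(chars))
  features <- matrix(0, n_total, p)
  row <- 0L
  for (k in seq_along(chars)) {
    sched <- unlist(lapply(seq_len(config$n_sequences_max),
                           function(i) sample.int(grid$n_groups)))
    for (i in seq_len(n_per_char)) {
      row <- row + 1L
      group[row] <- sched[i]
      tgt <- chars[k] %in% grid$groups[[sched[i]]]
      label[row] <- tgt
      mu <- if (tgt) sm$mu_target else sm$mu_nontarget
      sdv <- sqrt(if (tgt) sm$var_target else sm$var_nontarget)
      noise <- stats::rnorm(p, 0, sdv / sqrt(wnorm2))
      features[row, ] <- mu * wvec / wnorm2 + noise
    }
  }
  structure(
    list(features = features, label = label, group = group,
         character_index = character_index, flash_index = flash_index,
         target = config$target_text),
    class = "epoch_stream"
  )
}

#' Turn an epoch stream plus weights into a score stream
#'
#' Scores every epoch with the given weights and assembles the
#' `score_stream` table used by [decode_sequence()].
#'
#' @param epochs an `epoch_stream` from [simulate_epoch_features()] or
#'   [read_training_data()].
#' @param weights a `feature_weights`.
#' @param timing a [timing_model()] for the timestamps.
#' @param grid a [grid_layout()] attached to the stream.
#' @return a `score_stream` data frame.
#' @export
epochs_to_score_stream <- function(epochs, weights,
                                   timing = timing_model(),
                                   grid = grid_layout()) {
  stopifnot(inherits(epochs, "epoch_stream"))
  scores <- score_epoch(epochs$features, weights)
  ord <- order(epochs$character_index, epochs$flash_index)
  stream <- data.frame(
    character_index = epochs$character_index[ord],
    flash_index = epochs$flash_index[ord],
    group = epochs$group[ord],
    score = scores[ord],
    timestamp_ms = (seq_along(ord) - 1) * timing$soa_ms)
  attr(stream, "target") <- epochs$target
  attr(stream, "grid") <- grid
  class(stream) <- c("score_stream", "data.frame")
  stream
}
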