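#' Selection accuracy against a target phrase
#'
#' Fraction of output characters matching the target string position by
#' position. When the output is longer than the target the target is cycled
#' (subjects who finish the phrase start it again), controlled by
#' `cycle_target`.
#'
#' @param output decoded string (non-empty).
#' @param target intended string.
#' @param cycle_target compare position `i` against
#'   `target[(i - 1) %% nchar(target) + 1]` (default `TRUE`).
#' @return fraction in `[0, 1]`.
#' @examples
#' accuracy("CAR", "CAT")  # 2/3
#' @export
accuracy <- function(output, target, cycle_target = TRUE) {
  if (!nzchar(output)) stop("empty output string")
  out <- strsplit(output, "", fixed = TRUE)[[1]]
  tgt <- strsplit(target, "", fixed = TRUE)[[1]]
  if (!length(tgt)) stop("empty target string")
  idx <- if (cycle_target) ((seq_along(out) - 1) %% length(tgt)) + 1
         else seq_along(out)
  if (!cycle_target && length(out) > length(tgt))
    stop("output longer than target with cycling disabled")
  mean(out == tgt[idx])
}

#' Selection rate in selections per minute
#' @param n_selections number of selections made.
#' @param total_time elapsed time in seconds (> 0).
#' @return selections/min.
#' @export
selection_rate <- function(n_selections, total_time) {
  if (total_time <= 0) stop("total_time must be positive")
  60 * n_selections / total_time
}

#' Correct characters per minute
#' @param n_correct number of correct selections.
#' @param total_time elapsed time in seconds (> 0).
#' @return correct characters/min.
#' @export
ccpm <- function(n_correct, total_time) {
  if (total_time <= 0) stop("total_time must be positive")
  60 * n_correct / total_time
}

#' Wolpaw information transfer rate
#'
#' Bits per selection `B = log2(N) + P log2(P) + (1 - P) log2((1-P)/(N-1))`
#' times the selection rate, for `N` possible selections at accuracy `P`.
#' The limits `P = 0` and `P = 1` are handled exactly; `P = 1/N` gives 0.
#'
#' @param selection_rate selections per minute.
#' @param accuracy fraction in `[0, 1]`.
#' @param n_choices number of possible selections (default 36, the grid).
#' @return bits per minute.
#' @examples
#' wolpaw_bit_rate(12.20, 1.0)     # 12.20 * log2(36)
#' wolpaw_bit_rate(10, 1 / 36)     # 0
#' @export
wolpaw_bit_rate <- function(selection_rate, accuracy, n_choices = 36L) {
  stopifnot(n_choices >= 2, all(accuracy >= 0), all(accuracy <= 1))
  N <- n_choices
  P <- accuracy
  plogp <- ifelse(P == 0, 0, P * log2(P))
  qlogq <- ifelse(P == 1, 0, (1 - P) * log2((1 - P) / (N - 1)))
  selection_rate * (log2(N) + plogp + qlogq)
}

#' Metrics for one decoded session
#'
#' Assembles selection rate, accuracy, CCPM and Wolpaw bit rate from a
#' decode result, its ground-truth target and the stimulus timing.
#'
#' @param result a [decode_sequence()] result (or any list with `output`
#'   and `flash_counts`).
#' @param target ground-truth string.
#' @param timing a [timing_model()].
#' @param n_choices selection count for the bit rate.
#' @param cycle_target passed to [accuracy()].
#' @return list of class `session_metrics`: `selection_rate`, `accuracy`,
#'   `ccpm`, `bit_rate`, `n_selections`, `total_time`, `mean_flashes`.
#' @export
session_metrics <- function(result, target, timing = timing_model(),
                            n_choices = 36L, cycle_target = TRUE) {
  n_sel <- length(result$flash_counts)
  total_time <- sum(selection_time_seconds(result$flash_counts, timing))
  acc <- accuracy(result$output, target, cycle_target)
  sr <- selection_rate(n_sel, total_time)
  structure(
    list(selection_rate = sr, accuracy = acc,
         ccpm = ccpm(round(acc * n_sel), total_time),
         bit_rate = wolpaw_bit_rate(sr, acc, n_choices),
         n_selections = n_sel, total_time = total_time,
         mean_flashes = mean(result$flash_counts)),
    class = "session_metrics"
  )
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(
    "<session_metrics: SR %.2f sel/min, ACC %.1f%%, CCPM %.2f, ITR %.2f bits/min>\n",
    x$selection_rate, 100 * x$accuracy, x$ccpm, x$bit_rate))
  invisible(x)
}

#' Threshold sweep over recorded or simulated sessions
#'
#' Replays each session's score stream through the decoder at every
#' threshold in the grid, averages the metrics over sessions per threshold,
#' and reports the threshold maximizing CCPM (ties going to the lower
#' threshold). This is the offline per-subject optimization of the dynamic
#' stopping threshold.
#'
#' @param sessions list of `score_stream` objects (each carrying its
#'   `target` attribute).
#' @param model a `language_model`.
#' @param score_model a [score_model()].
#' @param grid a [grid_layout()].
#' @param config a [decoder_config()]; its `threshold` entry is overridden.
#' @param thresholds numeric grid in `[0, 1]`; default `seq(0, 1, 0.01)`
#'   (101 values).
#' @param timing a [timing_model()].
#' @return list of class `threshold_sweep`: `table` (data frame with one
#'   row per threshold: `threshold`, `selection_rate`, `accuracy`, `ccpm`,
#'   `bit_rate`, `mean_flashes`) and `best_threshold`.
#' @export
threshold_sweep <- function(sessions, model, score_model,
                            grid = grid_layout(),
                            config = decoder_config(),
                            thresholds = seq(0, 1, by = 0.01),
                            timing = timing_model()) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  if (inherits(sessions, "score_stream")) sessions <- list(sessions)
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$threshold <- th
    ms <- lapply(sessions, function(st) {
      res <- decode_sequence(st, model, score_model, grid, cfg)
      session_metrics(res, attr(st, "target"), timing,
                      n_choices = length(grid$characters))
    })
    avg <- function(f) mean(vapply(ms, `[[`, numeric(1), f))
    data.frame(threshold = th, selection_rate = avg("selection_rate"),
               accuracy = avg("accuracy"), ccpm = avg("ccpm"),
               bit_rate = avg("bit_rate"), mean_flashes = avg("mean_flashes"))
  })
  tab <- do.call(rbind, rows)
  best <- tab$threshold[which.max(tab$ccpm)]  # first max = lowest threshold
  structure(list(table = tab, best_threshold = best),
            class = "threshold_sweep")
}

#' Three-fold offline cross-validation
#'
#' Mirrors the retrospective analysis of copy-spelling training data: with
#' the three training sessions as folds, each fold's decoder is trained
#' (SWLDA feature selection, then the Gaussian score model) on the other
#' two sessions and evaluated by decoding the held-out session.
#'
#' @param sessions list of exactly 3 `epoch_stream` objects (labeled
#'   training epochs with flash annotations and a `target`).
#' @param model a `language_model`.
#' @param grid a [grid_layout()].
#' @param config a [decoder_config()].
#' @param timing a [timing_model()].
#' @param p_enter,p_remove,max_features passed to [fit_swlda()].
#' @return list of class `crossfold_result`: `folds` (list of per-fold
#'   `session_metrics`) and `mean` (their field-wise average).
#' @export
crossfold_offline <- function(sessions, model, grid = grid_layout(),
                              config = decoder_config(),
                              timing = timing_model(),
                              p_enter = 0.10, p_remove = 0.15,
                              max_features = 60L) {
  if (length(sessions) != 3L)
    stop("three-fold cross-validation needs exactly 3 sessions")
  folds <- lapply(seq_along(sessions), function(k) {
    train <- sessions[-k]
    x <- do.call(rbind, lapply(train, `[[`, "features"))
    y <- unlist(lapply(train, `[[`, "label"))
    w <- fit_swlda(x, y, p_enter, p_remove, max_features)
    sm <- fit_score_model(score_epoch(x, w), y)
    held <- sessions[[k]]
    stream <- epochs_to_score_stream(held, w, timing, grid)
    res <- decode_sequence(stream, model, sm, grid, config)
    session_metrics(res, held$target, timing,
                    n_choices = length(grid$characters))
  })
  fields <- c("selection_rate", "accuracy", "ccpm", "bit_rate",
              "n_selections", "total_time", "mean_flashes")
  avg <- lapply(fields, function(f)
    mean(vapply(folds, `[[`, numeric(1), f)))
  names(avg) <- fields
  structure(list(folds = folds, mean = avg), class = "crossfold_result")
}
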