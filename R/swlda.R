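#' Stepwise linear discriminant analysis (SWLDA) feature selection
#'
#' Selects a sparse set of epoch features by stepwise ordinary-least-squares
#' regression of the binary target/non-target label on the features: each
#' forward step adds the candidate with the smallest partial p-value when it
#' falls below `p_enter`, each backward step removes included features whose
#' p-value exceeds `p_remove`, until either `max_features` features are held
#' or a fixed point is reached. The fitted OLS coefficients over the selected
#' features form the linear scoring function applied to each stimulus epoch.
#'
#' Forward p-values are computed by the Frisch-Waugh projection (residualize
#' the label and every candidate on the current design, then a one-variable
#' t-test), which is algebraically the full-model partial t-test. Ties are
#' broken towards the lowest feature index, so the fit is deterministic.
#'
#' @param x numeric matrix, epochs x features (e.g. from
#'   [preprocess_epoch()] rows bound together).
#' @param labels logical or 0/1 vector: `TRUE`/1 for target epochs.
#' @param p_enter forward inclusion significance level (default 0.10).
#' @param p_remove backward removal significance level (default 0.15, must
#'   exceed `p_enter`).
#' @param max_features cap on the number of selected features (default 60).
#' @return object of class `feature_weights`: `selected` (integer feature
#'   indices in selection order), `coefficients` (matching OLS weights),
#'   `n_features` (width of the training matrix).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 100, 6)
#' y <- x[, 3] > 0
#' w <- fit_swlda(x, y)
#' w$selected[1]  # 3
#' @export
fit_swlda <- function(x, labels, p_enter = 0.10, p_remove = 0.15,
                      max_features = 60L) {
  x <- as.matrix(x)
  y <- as.numeric(labels)
  stopifnot(nrow(x) == length(y), max_features >= 1)
  if (p_enter >= p_remove) stop("p_enter must be smaller than p_remove")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate design: all features are constant")

  n <- nrow(x)
  included <- integer(0)

  partial_pvalues <- function(candidates) {
    # residualize y and candidates on [1 | x[, included]]
    design <- cbind(1, x[, included, drop = FALSE])
    qrd <- qr(design)
    ry <- qr.resid(qrd, y)
    rx <- qr.resid(qrd, x[, candidates, drop = FALSE])
    ss <- colSums(rx^2)
    df <- n - ncol(design) - 1L
    p <- rep(NA_real_, length(candidates))
    ok <- ss > 1e-12 * n & df > 0
    if (any(ok)) {
      b <- colSums(rx[, ok, drop = FALSE] * ry) / ss[ok]
      rss <- sum(ry^2) - b^2 * ss[ok]
      rss[rss < 0] <- 0
      tt <- b / sqrt(pmax(rss / df, .Machine$double.xmin) / ss[ok])
      p[ok] <- 2 * stats::pt(-abs(tt), df)
    }
    p
  }

  included_pvalues <- function() {
    df <- as.data.frame(x[, included, drop = FALSE])
    names(df) <- paste0("f", seq_along(included))
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    # aliased (collinear) features are dropped by lm: mark for removal;
    # non-computable p under a perfect fit keeps the feature
    p <- rep(1, length(included))
    rows <- match(paste0("f", seq_along(included)), rownames(sm))
    for (i in seq_along(included)) {
      if (!is.na(rows[i])) {
        pv <- sm[rows[i], 4]
        p[i] <- if (is.finite(pv)) pv else 0
      }
    }
    p
  }

  repeat {
    changed <- FALSE
    if (length(included) < max_features) {
      candidates <- setdiff(seq_len(ncol(x)), included)
      if (length(candidates)) {
        p <- partial_pvalues(candidates)
        if (any(!is.na(p)) && min(p, na.rm = TRUE) < p_enter) {
          best <- candidates[which(p == min(p, na.rm = TRUE))[1]]
          included <- c(included, best)
          changed <- TRUE
        }
      }
    }
    while (length(included) > 0L) {
      p <- included_pvalues()
      if (max(p) <= p_remove) break
      worst <- which(p == max(p))[1]
      included <- included[-worst]
      changed <- TRUE
    }
    if (!changed || length(included) >= max_features) break
  }

  coefficients <- numeric(0)
  if (length(included)) {
    fit <- stats::lm.fit(cbind(1, x[, included, drop = FALSE]), y)
    coefficients <- unname(fit$coefficients[-1])
  }
  structure(
    list(selected = included, coefficients = coefficients,
         n_features = ncol(x)),
    class = "feature_weights"
  )
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights: %d of %d features selected>\n",
              length(x$selected), x$n_features))
  invisible(x)
}

#' Score a stimulus epoch with fitted feature weights
#'
#' The scalar stimulus score is the dot product of the selected-feature
#' coefficients with the epoch's values at those features.
#'
#' @param epoch numeric feature vector (or epochs x features matrix) with
#'   `weights$n_features` columns/entries.
#' @param weights a [fit_swlda()] result.
#' @return numeric score (vector when `epoch` is a matrix).
#' @export
score_epoch <- function(epoch, weights) {
  stopifnot(inherits(weights, "feature_weights"))
  if (is.matrix(epoch)) {
    if (ncol(epoch) != weights$n_features)
      stop("epoch has ", ncol(epoch), " features; weights expect ",
           weights$n_features)
    if (!length(weights$selected)) return(numeric(nrow(epoch)))
    return(drop(epoch[, weights$selected, drop = FALSE] %*%
                  weights$coefficients))
  }
  if (length(epoch) != weights$n_features)
    stop("epoch has ", length(epoch), " features; weights expect ",
         weights$n_features)
  if (!length(weights$selected)) return(0)
  sum(epoch[weights$selected] * weights$coefficients)
}

#' Gaussian score model for target and non-target stimuli
#'
#' Per-class sample mean and unbiased (n-1) sample variance of the stimulus
#' scores; these four numbers parameterize the decoding likelihood
#' N(mu_target, var_target) / N(mu_nontarget, var_nontarget).
#'
#' @param scores numeric stimulus scores.
#' @param labels logical or 0/1 vector, `TRUE`/1 marking target epochs.
#' @return object of class `score_model` with `mu_target`, `var_target`,
#'   `mu_nontarget`, `var_nontarget`.
#' @examples
#' fit_score_model(c(1, 3, 0, 0, 0, 2), c(1, 1, 0, 0, 0, 0))
#' @export
fit_score_model <- function(scores, labels) {
  lab <- as.logical(labels)
  stopifnot(length(scores) == length(lab))
  if (sum(lab) < 2L || sum(!lab) < 2L)
    stop("need at least 2 scores in each class")
  vt <- stats::var(scores[lab]); vn <- stats::var(scores[!lab])
  if (vt == 0 || vn == 0)
    stop("zero-variance scores: degenerate training data")
  score_model(mean(scores[lab]), vt, mean(scores[!lab]), vn)
}

#' @rdname fit_score_model
#' @param mu_target,var_target,mu_nontarget,var_nontarget Gaussian
#'   parameters; variances must be non-negative (zero only meaningful for
#'   generating noise-free simulations, never for decoding).
#' @export
score_model <- function(mu_target, var_target, mu_nontarget, var_nontarget) {
  if (!is.finite(var_target) || !is.finite(var_nontarget) ||
      var_target < 0 || var_nontarget < 0)
    stop("score variances must be non-negative")
  structure(
    list(mu_target = mu_target, var_target = var_target,
         mu_nontarget = mu_nontarget, var_nontarget = var_nontarget),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf(
    "<score_model: target N(%.3g, %.3g), non-target N(%.3g, %.3g)>\n",
    x$mu_target, x$var_target, x$mu_nontarget, x$var_nontarget))
  invisible(x)
}

#' Reduce a raw post-stimulus window to epoch features
#'
#' Takes the multichannel window following a flash (by default 32 channels x
#' 154 samples, i.e. 600 ms at 256 Hz), block-averages each channel over
#' non-overlapping windows of `decimation_factor` samples (a moving average
#' followed by downsampling at the same factor), and flattens channel-major.
#' Trailing samples that do not fill a block are dropped.
#'
#' @param raw_window numeric matrix, channels x samples.
#' @param decimation_factor block length in samples (default 12, i.e. about
#'   21 Hz effective rate from 256 Hz).
#' @param expected_dim optional `c(channels, samples)` to validate against.
#' @return numeric feature vector of length
#'   `channels * floor(samples / decimation_factor)`, channel-major (all
#'   decimated samples of channel 1 first).
#' @export
preprocess_epoch <- function(raw_window, decimation_factor = 12L,
                             expected_dim = NULL) {
  if (!is.matrix(raw_window)) stop("raw_window must be a channels x samples matrix")
  if (!is.null(expected_dim) && !all(dim(raw_window) == expected_dim))
    stop("window is ", paste(dim(raw_window), collapse = "x"),
         "; expected ", paste(expected_dim, collapse = "x"))
  d <- as.integer(decimation_factor)
  stopifnot(d >= 1)
  nblock <- floor(ncol(raw_window) / d)
  if (nblock < 1) stop("decimation factor exceeds the window length")
  kept <- raw_window[, seq_len(nblock * d), drop = FALSE]
  # channel-wise block means: reshape samples into d x nblock per channel
  out <- t(apply(kept, 1, function(ch) colMeans(matrix(ch, nrow = d))))
  if (nblock == 1L) out <- matrix(out, ncol = 1L)
  as.vector(t(out))
}
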