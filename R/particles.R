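#' Particle set over typed-string hypotheses
#'
#' A particle is one hypothesis of the full output string, carried with an
#' importance weight. The set starts with empty histories and uniform
#' weights `1/P`; weights are stored in the log domain because a character
#' period multiplies up to 120 Gaussian densities into the weight.
#'
#' @param P number of particles (>= 1).
#' @param seed optional integer; when supplied, `set.seed(seed)` is called so
#'   the downstream proposal/resampling draws are reproducible.
#' @return object of class `particle_set`: `history` (character vector of
#'   length `P`), `log_weight` (normalized so weights sum to 1), `P`.
#' @examples
#' ps <- initialize_particles(4)
#' particle_weights(ps)  # 0.25 0.25 0.25 0.25
#' @export
initialize_particles <- function(P, seed = NULL) {
  P <- as.integer(P)
  if (is.na(P) || P < 1L) stop("P must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(history = rep("", P), log_weight = rep(-log(P), P), P = P),
    class = "particle_set"
  )
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set: P = %d, %d distinct histories>\n",
              x$P, length(unique(x$history))))
  invisible(x)
}

#' Normalized particle weights
#' @param particles a `particle_set`.
#' @return numeric vector summing to 1.
#' @export
particle_weights <- function(particles) {
  lw <- particles$log_weight
  w <- exp(lw - max(lw))
  w / sum(w)
}

last_chars <- function(particles) {
  substr(particles$history, nchar(particles$history),
         nchar(particles$history))
}

#' Propose the next character for every particle
#'
#' Extends each particle's history by one character drawn from the language
#' model's transition distribution conditioned on that particle's current
#' word fragment (its history since the last separator). Weights are left
#' unchanged: the proposal equals the prior, so the importance weights need
#' only ever absorb the likelihood.
#'
#' @param particles a `particle_set`.
#' @param model a `language_model` whose vocabulary matches the grid.
#' @return the extended `particle_set`.
#' @export
propose_next_character <- function(particles, model) {
  stopifnot(inherits(particles, "particle_set"),
            inherits(model, "language_model"))
  frag <- word_fragment(particles$history, model$separator)
  new_char <- character(particles$P)
  for (f in unique(frag)) {
    idx <- which(frag == f)
    p <- transition_probabilities(model, f)
    new_char[idx] <- sample(model$vocabulary, length(idx),
                            replace = TRUE, prob = p)
  }
  particles$history <- paste0(particles$history, new_char)
  particles
}

#' Reweight particles with one flash observation
#'
#' Multiplies each particle's weight by the Gaussian likelihood of the
#' observed stimulus score: the target density `N(mu_target, var_target)`
#' when the flashed row/column contains the particle's current character,
#' otherwise the non-target density. Accumulation is in the log domain and
#' the weights are renormalized to sum to 1.
#'
#' @param particles a `particle_set` whose histories are non-empty.
#' @param group flashed group index (1-based into `grid$groups`).
#' @param score observed stimulus score for that flash.
#' @param score_model a [score_model()].
#' @param grid a [grid_layout()].
#' @return the reweighted `particle_set`.
#' @export
update_weights <- function(particles, group, score, score_model, grid) {
  stopifnot(inherits(particles, "particle_set"),
            inherits(score_model, "score_model"),
            inherits(grid, "grid_layout"))
  if (group < 1 || group > grid$n_groups) stop("flash group out of range")
  if (score_model$var_target <= 0 || score_model$var_nontarget <= 0)
    stop("decoding requires strictly positive score variances")
  cur <- last_chars(particles)
  if (any(!nzchar(cur)))
    stop("particles have empty histories; propose a character first")
  in_group <- cur %in% grid$groups[[group]]
  ll <- ifelse(
    in_group,
    stats::dnorm(score, score_model$mu_target,
                 sqrt(score_model$var_target), log = TRUE),
    stats::dnorm(score, score_model$mu_nontarget,
                 sqrt(score_model$var_nontarget), log = TRUE))
  lw <- particles$log_weight + ll
  m <- max(lw)
  if (!is.finite(m)) stop("all particle weights underflowed to zero")
  particles$log_weight <- lw - (m + log(sum(exp(lw - m))))
  particles
}

#' Posterior over the current character
#'
#' Sums the normalized weights of all particles whose history ends in each
#' grid character (the Kronecker-delta histogram of the particle
#' approximation).
#'
#' @param particles a `particle_set` with non-empty histories.
#' @param grid a [grid_layout()].
#' @return named numeric vector over `grid$characters`, summing to 1.
#' @export
character_posterior <- function(particles, grid = grid_layout()) {
  cur <- last_chars(particles)
  if (any(!nzchar(cur))) stop("particles have empty histories")
  w <- particle_weights(particles)
  post <- vapply(split(w, factor(cur, levels = grid$characters)), sum,
                 numeric(1))
  post / sum(w)
}

#' Systematic resampling of the particle set
#'
#' Draws a fresh population of `P` particles proportional to the current
#' weights using systematic resampling (one uniform offset, `P` evenly
#' spaced strata), then resets every weight to `1/P`. The multiplicity of a
#' particle with weight `w` is guaranteed to lie in
#' `{floor(P w), ceiling(P w)}`.
#'
#' @param particles a `particle_set`.
#' @return the resampled `particle_set`.
#' @export
resample <- function(particles) {
  w <- particle_weights(particles)
  if (!any(w > 0)) stop("cannot resample: all weights are zero")
  P <- particles$P
  u <- (stats::runif(1) + seq_len(P) - 1) / P
  idx <- findInterval(u, cumsum(w), left.open = TRUE) + 1L
  idx[idx > P] <- P  # guard against cumsum rounding at the top stratum
  particles$history <- particles$history[idx]
  particles$log_weight <- rep(-log(P), P)
  particles
}
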