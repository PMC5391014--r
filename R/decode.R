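#' Decoder configuration
#'
#' Bundles the decoding parameters: the dynamic-stopping posterior threshold
#' (default 0.95), the flash cap per character (default 120, i.e. ten full
#' 12-flash sequences), the minimum number of flashes before the stopping
#' rule may fire (default one full sequence of 12, so a decision is never
#' made on the language prior alone), the particle count, the language-model
#' smoothing floor, whether selected characters are hard-committed into all
#' particle histories, and the master seed.
#'
#' @param threshold posterior probability needed to stop early, in `[0, 1]`.
#' @param max_flashes flash cap per character.
#' @param min_flashes flashes that must elapse before early stopping.
#' @param P particle count.
#' @param seed master RNG seed for proposals and resampling.
#' @param smoothing_floor language-model floor used when a model is built by
#'   a front end from this config.
#' @param commit_selected when `TRUE` (default) every particle's current
#'   character is overwritten with the selected one after each decision, so
#'   all particles agree with the displayed output string.
#' @return a list of class `decoder_config`.
#' @export
decoder_config <- function(threshold = 0.95, max_flashes = 120L,
                           min_flashes = 12L, P = 1000L, seed = 1L,
                           smoothing_floor = 0.05, commit_selected = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1, max_flashes >= 12,
            min_flashes >= 1, P >= 1)
  structure(
    list(threshold = threshold, max_flashes = as.integer(max_flashes),
         min_flashes = as.integer(min_flashes), P = as.integer(P),
         seed = as.integer(seed), smoothing_floor = smoothing_floor,
         commit_selected = isTRUE(commit_selected)),
    class = "decoder_config"
  )
}

#' Read / write a decoder configuration as a key-value file
#'
#' @param path YAML key-value file; keys are the [decoder_config()]
#'   arguments, missing keys take the defaults.
#' @param config a `decoder_config`.
#' @return `read_decoder_config` returns a `decoder_config`;
#'   `write_decoder_config` returns `path` invisibly.
#' @export
read_decoder_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(decoder_config)))
  do.call(decoder_config, vals[keep])
}

#' @rdname read_decoder_config
#' @export
write_decoder_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Decode one character with dynamic stopping
#'
#' Consumes flash events one at a time, reweighting the particle set after
#' each and monitoring the posterior over the current character. Flashing
#' stops at the first flash — once at least `min_flashes` have been seen —
#' at which some character's posterior reaches `threshold`, or when
#' `max_flashes` have been consumed, whichever comes first. The character
#' with the highest posterior is selected (ties broken by grid row-major
#' order). The particle set is then resampled; with `commit_selected` the
#' last character of every history is first replaced by the selection.
#'
#' @param groups integer vector of flashed group indices for this character
#'   period, in presentation order.
#' @param scores numeric vector of stimulus scores, parallel to `groups`.
#' @param particles a `particle_set` whose histories already include a
#'   hypothesis for the current character (see [propose_next_character()]).
#' @param score_model a [score_model()].
#' @param grid a [grid_layout()].
#' @param config a [decoder_config()].
#' @return list with `selected` (character), `n_flashes` (flashes consumed),
#'   `posterior` (posterior over the grid at the stopping flash),
#'   `trace` (matrix, flashes x characters, the full posterior trace) and
#'   `particles` (the resampled set, ready for the next character).
#' @export
decode_character <- function(groups, scores, particles, score_model,
                             grid = grid_layout(),
                             config = decoder_config()) {
  stopifnot(length(groups) == length(scores))
  if (length(groups) < min(config$min_flashes, config$max_flashes))
    stop("flash stream exhausted before a legal stopping point (",
         length(groups), " < ", config$min_flashes, " flashes)")
  n_avail <- min(length(groups), config$max_flashes)
  trace <- matrix(NA_real_, nrow = n_avail, ncol = length(grid$characters),
                  dimnames = list(NULL, grid$characters))
  used <- n_avail
  for (i in seq_len(n_avail)) {
    particles <- update_weights(particles, groups[i], scores[i],
                                score_model, grid)
    post <- character_posterior(particles, grid)
    trace[i, ] <- post
    if (i >= config$min_flashes && max(post) >= config$threshold) {
      used <- i
      break
    }
  }
  post <- trace[used, ]
  selected <- grid$characters[which.max(post)]
  if (config$commit_selected) {
    h <- particles$history
    substr(h, nchar(h), nchar(h)) <- selected
    particles$history <- h
  }
  particles <- resample(particles)
  list(selected = selected, n_flashes = used, posterior = post,
       trace = trace[seq_len(used), , drop = FALSE], particles = particles)
}

#' Decode a full spelling session
#'
#' Runs the complete particle-filter loop over a score stream: for each
#' character period, propose a continuation for every particle from the
#' language model, consume that period's flashes under dynamic stopping,
#' select the posterior argmax, and resample. The master seed in `config`
#' makes the whole decode reproducible.
#'
#' @param stream a `score_stream` (see [simulate_session()] /
#'   [read_score_stream()]): a data frame with columns `character_index`,
#'   `flash_index`, `group`, `score`, `timestamp_ms`.
#' @param model a `language_model`.
#' @param score_model a [score_model()].
#' @param grid a [grid_layout()].
#' @param config a [decoder_config()].
#' @return list of class `decode_result`: `output` (decoded string),
#'   `flash_counts` (integer vector per character), `posteriors` (list of
#'   stopping-flash posteriors).
#' @export
decode_sequence <- function(stream, model, score_model,
                            grid = grid_layout(),
                            config = decoder_config()) {
  stopifnot(is.data.frame(stream))
  req <- c("character_index", "flash_index", "group", "score")
  if (!all(req %in% names(stream)))
    stop("stream must have columns ", paste(req, collapse = ", "))
  if (any(stream$group < 1 | stream$group > grid$n_groups))
    stop("stream flash groups are inconsistent with the grid")
  set.seed(config$seed)
  particles <- initialize_particles(config$P)
  chars <- sort(unique(stream$character_index))
  out <- character(length(chars))
  n_flashes <- integer(length(chars))
  posteriors <- vector("list", length(chars))
  for (k in seq_along(chars)) {
    block <- stream[stream$character_index == chars[k], , drop = FALSE]
    block <- block[order(block$flash_index), , drop = FALSE]
    particles <- propose_next_character(particles, model)
    dec <- decode_character(block$group, block$score, particles,
                            score_model, grid, config)
    out[k] <- dec$selected
    n_flashes[k] <- dec$n_flashes
    posteriors[[k]] <- dec$posterior
    particles <- dec$particles
  }
  structure(
    list(output = paste(out, collapse = ""), flash_counts = n_flashes,
         posteriors = posteriors),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat("<decode_result>\n  output: ", x$output, "\n  flashes: ",
      paste(x$flash_counts, collapse = " "), "\n", sep = "")
  invisible(x)
}
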