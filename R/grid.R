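#' Speller grid layout
#'
#' Constructs the character matrix used by the row/column speller paradigm
#' together with its flash groups. Characters are laid out row-major; groups
#' `1:n_rows` are the rows and groups `(n_rows+1):(n_rows+n_cols)` the
#' columns, so every character belongs to exactly one row group and one
#' column group.
#'
#' The default is the classical 6x6 matrix: the letters A-Z, the digits 1-9,
#' and `"_"` (the word separator) in row-major order.
#'
#' @param characters character vector of single symbols, row-major. Length
#'   must equal `n_rows * n_cols` and symbols must be unique.
#' @param n_rows,n_cols grid dimensions.
#' @return An object of class `grid_layout` with elements `characters`,
#'   `n_rows`, `n_cols`, `groups` (list of character vectors, rows first)
#'   and `n_groups`.
#' @examples
#' g <- grid_layout()
#' g$groups[[1]]   # first row: A-F
#' g$groups[[7]]   # first column: A,G,M,S,Y,4
#' @export
grid_layout <- function(characters = c(LETTERS, as.character(1:9), "_"),
                        n_rows = 6L, n_cols = 6L) {
  characters <- as.character(characters)
  if (length(characters) != n_rows * n_cols)
    stop("grid needs exactly ", n_rows * n_cols, " characters")
  if (anyDuplicated(characters))
    stop("grid characters must be unique")
  if (any(nchar(characters) != 1L))
    stop("grid entries must be single characters")
  mat <- matrix(characters, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  groups <- c(
    lapply(seq_len(n_rows), function(r) mat[r, ]),
    lapply(seq_len(n_cols), function(cc) mat[, cc])
  )
  structure(
    list(characters = characters, n_rows = n_rows, n_cols = n_cols,
         groups = groups, n_groups = n_rows + n_cols),
    class = "grid_layout"
  )
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout: %d x %d, %d flash groups>\n",
              x$n_rows, x$n_cols, x$n_groups))
  print(matrix(x$characters, nrow = x$n_rows, byrow = TRUE), quote = FALSE)
  invisible(x)
}

#' Membership matrix of characters in flash groups
#'
#' @param grid a [grid_layout()].
#' @return logical matrix, `n_groups` x `length(grid$characters)`; entry
#'   `[g, k]` is `TRUE` when character `k` lies in flash group `g`.
#' @keywords internal
group_membership <- function(grid) {
  m <- vapply(grid$groups, function(gr) grid$characters %in% gr,
              logical(length(grid$characters)))
  t(m)
}

#' Stimulus timing model
#'
#' Flash timing for the speller: a stimulus onset asynchrony (SOA) made up of
#' the flash duration plus the interstimulus interval, and an optional pause
#' between character selections. Defaults follow the usual online protocol:
#' 100 ms flash, 25 ms ISI, 125 ms SOA, no inter-character pause.
#'
#' @param flash_ms flash duration in milliseconds.
#' @param isi_ms interstimulus interval in milliseconds.
#' @param inter_character_pause_ms pause added once per selection, ms.
#' @return object of class `timing_model` with fields `soa_ms`, `flash_ms`,
#'   `isi_ms`, `inter_character_pause_ms`.
#' @export
timing_model <- function(flash_ms = 100, isi_ms = 25,
                         inter_character_pause_ms = 0) {
  stopifnot(flash_ms > 0, isi_ms >= 0, inter_character_pause_ms >= 0)
  structure(
    list(soa_ms = flash_ms + isi_ms, flash_ms = flash_ms, isi_ms = isi_ms,
         inter_character_pause_ms = inter_character_pause_ms),
    class = "timing_model"
  )
}

#' Randomized flash schedule
#'
#' Concatenates `n_sequences` independent random permutations of the flash
#' groups, so each group flashes exactly once per sequence and any fixed
#' target character is flashed exactly twice per sequence (its row and its
#' column).
#'
#' @param n_sequences number of full sequences.
#' @param grid a [grid_layout()].
#' @param seed optional integer seed; when given, the schedule is drawn from
#'   a local RNG state and the caller's RNG is untouched.
#' @return integer vector of group indices, length `n_sequences * n_groups`.
#' @export
make_flash_schedule <- function(n_sequences, grid = grid_layout(),
                                seed = NULL) {
  stopifnot(n_sequences >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  unlist(lapply(seq_len(n_sequences), function(i) sample.int(grid$n_groups)))
}

#' Time needed for a selection
#'
#' Converts a flash count into seconds: `n_flashes * soa / 1000` plus the
#' configured inter-character pause. This is the arithmetic behind the
#' selection rate (selections per minute is its inverse times 60).
#'
#' @param n_flashes flashes used for the selection (>= 1).
#' @param timing a [timing_model()].
#' @return time in seconds.
#' @examples
#' selection_time_seconds(120, timing_model())  # 15 s
#' selection_time_seconds(12, timing_model())   # 1.5 s
#' @export
selection_time_seconds <- function(n_flashes, timing = timing_model()) {
  stopifnot(all(n_flashes >= 1))
  n_flashes * timing$soa_ms / 1000 + timing$inter_character_pause_ms / 1000
}
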