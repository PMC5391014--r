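#' Build a word-prefix language model from a text corpus
#'
#' Counts, for every prefix of every word in the corpus, how many corpus
#' words begin with that prefix. The count ratio
#' `c(history + char) / c(history)` then defines the character transition
#' probabilities used as the particle-filter proposal distribution.
#'
#' Normalization: text is folded to upper case and every character outside
#' the vocabulary (including whitespace) is treated as a word separator.
#' Characters dropped this way are reported once via a warning. The word
#' separator symbol itself (`"_"` in the default grid) receives transition
#' probability proportional to the number of corpus words *equal* to the
#' current history, i.e. the probability that the word ends there.
#'
#' Smoothing: a fixed probability mass `smoothing_floor` is spread uniformly
#' over the whole vocabulary and mixed with the count-ratio distribution, so
#' no grid character is ever unreachable regardless of the corpus.
#'
#' @param corpus_text a character vector of text (lines are concatenated),
#'   or a length-1 path handled by [read_corpus()] upstream.
#' @param vocabulary character vector of unique single symbols, must contain
#'   `separator`.
#' @param smoothing_floor total probability mass (0..1) reserved for the
#'   uniform floor; default 0.05.
#' @param separator the word-boundary symbol within the vocabulary.
#' @return object of class `language_model` with fields `vocabulary`,
#'   `separator`, `smoothing_floor`, `prefix_counts` (environment:
#'   prefix -> number of words starting with it), `word_counts`
#'   (environment: word -> exact occurrences) and `n_words`.
#' @examples
#' lm <- build_language_model("THE THE CAT", smoothing_floor = 0)
#' prefix_count(lm, "TH")            # 2
#' transition_probabilities(lm, "T") # all mass on "H"
#' @export
build_language_model <- function(corpus_text,
                                 vocabulary = c(LETTERS, as.character(1:9), "_"),
                                 smoothing_floor = 0.05,
                                 separator = "_") {
  vocabulary <- as.character(vocabulary)
  if (anyDuplicated(vocabulary)) stop("vocabulary has duplicate characters")
  if (!separator %in% vocabulary) stop("vocabulary must contain the separator")
  if (smoothing_floor < 0 || smoothing_floor > 1)
    stop("smoothing_floor must be in [0, 1]")

  words <- tokenize_corpus(corpus_text, vocabulary, separator)
  if (length(words) == 0L)
    stop("empty corpus: no valid word survives normalization")

  prefix_counts <- new.env(parent = emptyenv(), hash = TRUE)
  word_counts <- new.env(parent = emptyenv(), hash = TRUE)
  tab <- table(words)
  for (w in names(tab)) {
    n <- as.integer(tab[[w]])
    assign(w, n + (if (exists(w, word_counts, inherits = FALSE))
      get(w, word_counts) else 0L), envir = word_counts)
    for (k in seq_len(nchar(w))) {
      p <- substr(w, 1L, k)
      old <- if (exists(p, prefix_counts, inherits = FALSE))
        get(p, prefix_counts) else 0L
      assign(p, old + n, envir = prefix_counts)
    }
  }

  structure(
    list(vocabulary = vocabulary, separator = separator,
         smoothing_floor = smoothing_floor,
         prefix_counts = prefix_counts, word_counts = word_counts,
         n_words = length(words)),
    class = "language_model"
  )
}

#' Normalize corpus text into vocabulary words
#'
#' Uppercases, maps every non-vocabulary character to a word boundary, and
#' splits into words. Warns (once) about characters dropped this way.
#'
#' @param corpus_text character vector.
#' @param vocabulary,separator as in [build_language_model()].
#' @return character vector of words (possibly empty).
#' @keywords internal
tokenize_corpus <- function(corpus_text, vocabulary, separator) {
  txt <- toupper(paste(corpus_text, collapse = " "))
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  # the separator and whitespace both mark boundaries, silently
  boundary <- chars == separator | grepl("[[:space:]]", chars)
  in_vocab <- chars %in% setdiff(vocabulary, separator)
  dropped <- unique(chars[!in_vocab & !boundary])
  if (length(dropped))
    warning("dropped non-vocabulary characters (treated as separators): ",
            paste(dropped, collapse = " "), call. = FALSE)
  chars[!in_vocab] <- " "
  words <- strsplit(paste(chars, collapse = ""), "[[:space:]]+")[[1]]
  words[nzchar(words)]
}

#' @export
print.language_model <- function(x, ...) {
  cat(sprintf(
    "<language_model: %d words, %d prefixes, |V| = %d, floor = %g>\n",
    x$n_words, length(ls(x$prefix_counts)), length(x$vocabulary),
    x$smoothing_floor))
  invisible(x)
}

#' Number of corpus words beginning with a prefix
#'
#' @param model a `language_model`.
#' @param prefix character string; `""` returns the total word count.
#' @return integer count.
#' @export
prefix_count <- function(model, prefix) {
  stopifnot(inherits(model, "language_model"))
  if (identical(prefix, "")) return(model$n_words)
  if (exists(prefix, model$prefix_counts, inherits = FALSE))
    get(prefix, model$prefix_counts) else 0L
}

#' Character transition probabilities given a word fragment
#'
#' For history `h` (the fragment of the current word typed so far; `""` at a
#' word start), the probability of continuing with character `v` is
#' proportional to `c(h + v)`, and the probability of the word separator is
#' proportional to the number of words exactly equal to `h`. The resulting
#' distribution is mixed with the uniform smoothing floor. A history with no
#' corpus support falls back to the uniform distribution (with a message).
#'
#' @param model a `language_model`.
#' @param history word fragment; must contain only non-separator vocabulary
#'   characters.
#' @return named numeric vector over the full vocabulary, summing to 1.
#' @export
transition_probabilities <- function(model, history = "") {
  stopifnot(inherits(model, "language_model"))
  V <- model$vocabulary
  nV <- length(V)
  uniform <- stats::setNames(rep(1 / nV, nV), V)
  hchars <- if (nzchar(history)) strsplit(history, "", fixed = TRUE)[[1]] else character()
  if (any(!hchars %in% setdiff(V, model$separator)))
    stop("history contains characters outside the (non-separator) vocabulary")

  denom <- prefix_count(model, history)
  if (denom == 0L) {
    if (model$n_words > 0L)  # a deliberately uniform model stays silent
      message("language model: unseen history '", history,
              "', falling back to the uniform distribution")
    return(uniform)
  }
  raw <- vapply(V, function(v) {
    if (v == model$separator) {
      w <- if (nzchar(history) &&
               exists(history, model$word_counts, inherits = FALSE))
        get(history, model$word_counts) else 0L
      w / denom
    } else {
      prefix_count(model, paste0(history, v)) / denom
    }
  }, numeric(1))
  fl <- model$smoothing_floor
  p <- (1 - fl) * raw + fl / nV
  # raw sums to 1 by the prefix-count telescoping identity; guard numerically
  p / sum(p)
}

#' Word fragment of a typed history
#'
#' The suffix of a typed string since the last word separator; this is the
#' history the language model conditions on.
#'
#' @param history full typed string(s).
#' @param separator word separator symbol.
#' @return character vector of fragments.
#' @export
word_fragment <- function(history, separator = "_") {
  sub(paste0(".*", sep_regex(separator)), "", history)
}

sep_regex <- function(separator) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", separator)
}

#' Read a plain-text corpus file
#'
#' @param path UTF-8 text file.
#' @return character vector of lines.
#' @export
read_corpus <- function(path) {
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Save / load a language model
#'
#' A versioned tab-separated key-value text format: a header recording the
#' vocabulary, separator, smoothing floor and word total, then one line per
#' stored count (`P` rows are prefix counts, `W` rows exact word counts).
#' The round trip is exact.
#'
#' @param model a `language_model`.
#' @param path file path.
#' @return `write_language_model` returns `path` invisibly;
#'   `read_language_model` returns the restored `language_model`.
#' @export
write_language_model <- function(model, path) {
  stopifnot(inherits(model, "language_model"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "#pfspeller-language-model v1",
    paste0("#vocabulary\t", paste(model$vocabulary, collapse = "")),
    paste0("#separator\t", model$separator),
    paste0("#smoothing_floor\t", format(model$smoothing_floor, digits = 17)),
    paste0("#n_words\t", model$n_words)
  ), con)
  for (p in sort(ls(model$prefix_counts)))
    writeLines(paste("P", p, get(p, model$prefix_counts), sep = "\t"), con)
  for (w in sort(ls(model$word_counts)))
    writeLines(paste("W", w, get(w, model$word_counts), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_language_model
#' @export
read_language_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || lines[1] != "#pfspeller-language-model v1")
    stop("not a pfspeller language model file: ", path)
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, "\t"), lines, value = TRUE)[1]
    sub(paste0("^#", key, "\t"), "", ln)
  }
  vocabulary <- strsplit(hdr("vocabulary"), "", fixed = TRUE)[[1]]
  model <- structure(
    list(vocabulary = vocabulary, separator = hdr("separator"),
         smoothing_floor = as.numeric(hdr("smoothing_floor")),
         prefix_counts = new.env(parent = emptyenv(), hash = TRUE),
         word_counts = new.env(parent = emptyenv(), hash = TRUE),
         n_words = as.integer(hdr("n_words"))),
    class = "language_model")
  body <- lines[!startsWith(lines, "#")]
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    env <- if (f[1] == "P") model$prefix_counts else model$word_counts
    assign(f[2], as.integer(f[3]), envir = env)
  }
  model
}

#' Uniform language model over a vocabulary
#'
#' Convenience constructor for the no-language-information baseline: every
#' transition distribution is uniform over the vocabulary.
#'
#' @param vocabulary character vector of unique symbols.
#' @param separator word separator symbol.
#' @return a `language_model` whose every history is unseen, hence uniform.
#' @export
uniform_language_model <- function(vocabulary = c(LETTERS, as.character(1:9), "_"),
                                   separator = "_") {
  m <- structure(
    list(vocabulary = as.character(vocabulary), separator = separator,
         smoothing_floor = 1,
         prefix_counts = new.env(parent = emptyenv(), hash = TRUE),
         word_counts = new.env(parent = emptyenv(), hash = TRUE),
         n_words = 0L),
    class = "language_model")
  m
}
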