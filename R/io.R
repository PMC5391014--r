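#' Read / write score-stream files
#'
#' A score stream is a tab-separated table with columns `character_index`,
#' `flash_index`, `group`, `score`, `timestamp_ms`. The hidden target text,
#' when known (simulated or copy-spelling sessions), travels in a sidecar
#' file `<path>.target` holding the string on one line.
#'
#' @param stream a `score_stream` data frame.
#' @param path file path for the TSV.
#' @param write_target write the ground-truth sidecar when the stream has a
#'   `target` attribute (default `TRUE`).
#' @return `write_score_stream` returns `path` invisibly;
#'   `read_score_stream` returns a `score_stream`.
#' @export
write_score_stream <- function(stream, path, write_target = TRUE) {
  req <- c("character_index", "flash_index", "group", "score",
           "timestamp_ms")
  stopifnot(all(req %in% names(stream)))
  utils::write.table(as.data.frame(stream)[req], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tgt <- attr(stream, "target")
  if (write_target && !is.null(tgt))
    writeLines(tgt, paste0(path, ".target"))
  invisible(path)
}

#' @rdname write_score_stream
#' @export
read_score_stream <- function(path) {
  stream <- utils::read.delim(path)
  req <- c("character_index", "flash_index", "group", "score",
           "timestamp_ms")
  missing <- setdiff(req, names(stream))
  if (length(missing))
    stop("score stream lacks columns: ", paste(missing, collapse = ", "))
  sidecar <- paste0(path, ".target")
  if (file.exists(sidecar))
    attr(stream, "target") <- readLines(sidecar, warn = FALSE)[1]
  class(stream) <- c("score_stream", "data.frame")
  stream
}

#' Read / write labeled training epochs
#'
#' Tab-separated, one row per epoch: `label` (0/1), `group`,
#' `character_index`, `flash_index`, then the flattened feature columns
#' `f1..fk`. The target text travels in a `<path>.target` sidecar.
#'
#' @param epochs an `epoch_stream` (see [simulate_epoch_features()]).
#' @param path file path.
#' @return `write_training_data` returns `path` invisibly;
#'   `read_training_data` returns an `epoch_stream`.
#' @export
write_training_data <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_stream"))
  tab <- data.frame(label = as.integer(epochs$label),
                    group = epochs$group,
                    character_index = epochs$character_index,
                    flash_index = epochs$flash_index)
  feat <- as.data.frame(epochs$features)
  names(feat) <- paste0("f", seq_len(ncol(feat)))
  utils::write.table(cbind(tab, feat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(epochs$target))
    writeLines(epochs$target, paste0(path, ".target"))
  invisible(path)
}

#' @rdname write_training_data
#' @export
read_training_data <- function(path) {
  tab <- utils::read.delim(path)
  meta <- c("label", "group", "character_index", "flash_index")
  missing <- setdiff(meta, names(tab))
  if (length(missing))
    stop("training data lacks columns: ", paste(missing, collapse = ", "))
  fcols <- grep("^f[0-9]+$", names(tab), value = TRUE)
  if (!length(fcols)) stop("training data has no feature columns f1..fk")
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  sidecar <- paste0(path, ".target")
  target <- if (file.exists(sidecar))
    readLines(sidecar, warn = FALSE)[1] else NULL
  structure(
    list(features = as.matrix(tab[fcols]), label = tab$label == 1,
         group = tab$group, character_index = tab$character_index,
         flash_index = tab$flash_index, target = target),
    class = "epoch_stream"
  )
}

#' Default corpus shipped with the package
#'
#' Path to a small synthetic plain-English text written for this package
#' (the original study never names its corpus), suitable for demonstrating
#' and testing the language model.
#'
#' @return file path.
#' @export
default_corpus_path <- function() {
  system.file("extdata", "corpus_default.txt", package = "pfspeller",
              mustWork = TRUE)
}
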