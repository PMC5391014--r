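#' Published per-subject performance tables
#'
#' Loads the packaged per-subject fixtures: `speller_table_offline` holds
#' the offline (three-fold cross-validated, dynamic stopping) selection
#' rate, accuracy and CCPM of the 10 subjects P-Y under three
#' condition/classifier pairs (inverting stimuli + particle filter,
#' famous-faces + SWLDA, famous-faces + particle filter);
#' `speller_table_online` holds the online copy-spelling results for the
#' two particle-filter conditions. Column names are
#' `<metric>_<condition>` with metrics `SR` (selections/min), `ACC`
#' (percent) and `CCPM` (characters/min), conditions `InvPF`, `FFSWLDA`,
#' `FFPF`.
#'
#' @param which `"offline"` or `"online"`.
#' @return data frame with a `Subject` column and numeric metric columns.
#' @export
load_subject_table <- function(which = c("offline", "online")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("subject_table_", which, ".tsv"),
                      package = "pfspeller", mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (nrow(tab) != 10L) stop("fixture must have the 10 subjects P-Y")
  if (anyNA(tab)) stop("fixture has missing cells")
  pc <- grep("^ACC_", names(tab), value = TRUE)
  if (any(tab[pc] < 0 | tab[pc] > 100)) stop("accuracies must be in [0,100]")
  tab
}

#' Column means and famous-faces improvements of a subject table
#'
#' Arithmetic means of every metric column, rounded to 2 decimals, plus —
#' whenever both an `_InvPF` and an `_FFPF` column exist for a metric —
#' the percent improvement `(FF - Inv) / Inv * 100` computed on the rounded
#' means and rounded to 1 decimal.
#'
#' @param table a subject table (see [load_subject_table()]).
#' @return list with `means` (named numeric, 2 decimals) and
#'   `improvements` (named numeric, 1 decimal; possibly empty).
#' @export
summarize_table <- function(table) {
  if (anyNA(table)) stop("missing cells in subject table")
  num <- vapply(table, is.numeric, logical(1))
  means <- round(colMeans(table[num]), 2)
  metrics <- unique(sub("_.*$", "", names(means)))
  improvements <- numeric(0)
  for (m in metrics) {
    inv <- paste0(m, "_InvPF"); ff <- paste0(m, "_FFPF")
    if (inv %in% names(means) && ff %in% names(means))
      improvements[m] <- round((means[[ff]] - means[[inv]]) /
                                 means[[inv]] * 100, 1)
  }
  list(means = means, improvements = improvements)
}

#' Per-subject Wolpaw bit rates from a subject table
#'
#' Computes each subject's information transfer rate from a condition's
#' selection-rate and accuracy columns.
#'
#' @param table a subject table.
#' @param condition condition suffix, e.g. `"InvPF"` or `"FFPF"`.
#' @param n_choices number of possible selections (default 36).
#' @return numeric vector of bits/min, one per subject.
#' @export
table_bit_rates <- function(table, condition, n_choices = 36L) {
  sr <- table[[paste0("SR_", condition)]]
  acc <- table[[paste0("ACC_", condition)]]
  if (is.null(sr) || is.null(acc))
    stop("table has no SR/ACC columns for condition ", condition)
  wolpaw_bit_rate(sr, acc / 100, n_choices)
}

#' Paired Wilcoxon signed-rank comparison of two conditions
#'
#' Convenience wrapper around [stats::wilcox.test()] for paired per-subject
#' metric columns. Exact p-values depend on tie/zero handling, so this is a
#' descriptive aid rather than a reproduction of published p-values.
#'
#' @param table a subject table.
#' @param metric `"SR"`, `"ACC"` or `"CCPM"`.
#' @param cond_a,cond_b condition suffixes.
#' @return the `htest` object.
#' @export
compare_conditions <- function(table, metric = "SR",
                               cond_a = "FFPF", cond_b = "InvPF") {
  a <- table[[paste0(metric, "_", cond_a)]]
  b <- table[[paste0(metric, "_", cond_b)]]
  if (is.null(a) || is.null(b)) stop("metric/condition columns not found")
  stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
}
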