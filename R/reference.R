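#' Published reference confusion matrices
#'
#' Per-source confusion matrices (TP/TN/FP/FN, class 1 = patient), reported
#' prediction accuracies and log Bayes factors from the multi-site ADHD
#' classification study that motivated this framework, for the three
#' cross-validation schemes and the multi-source combinations. They serve
#' as recomputation fixtures: accuracy and the independence test can be
#' re-evaluated from the cell counts alone.
#'
#' @return A tibble with columns `table` (scheme), `source`, `log_b10`,
#'   `pa` (both as reported), and the cells `tp`, `tn`, `fp`, `fn`.
#' @export
reference_confusions <- function() {
  path <- system.file("extdata", "reference_confusions.tsv", package = "sitewise")
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
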