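#' Published reference group summaries
#'
#' The back-transformed marginal means per experimental group and the
#' reported unpaired mean differences from a published photothrombotic
#' stroke study of AIS structure and intrinsic excitability, as printed
#' (differences oriented comparison minus reference, i.e. stroke - sham and
#' GFP+ - GFP-). These serve as inputs to arithmetic consistency checks:
#' the difference of the printed marginal means must reproduce the printed
#' mean difference for every outcome.
#'
#' @return A data frame with columns `outcome`, `units`, `reference_label`,
#'   `comparison_label`, `emm_reference`, `emm_comparison`, `printed_diff`.
#' @export
reference_group_summaries <- function() {
  path <- system.file("extdata", "reference_group_summaries.csv",
                      package = "aisephys", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}
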