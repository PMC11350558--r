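#' Published benchmark variability tables for healthy mice
#'
#' Reference values from the repeated-sampling validation of the built-in
#' peripheral-blood panels (5 healthy adult mice sampled on 5 occasions over
#' two weeks): per-variable eta-squared shares of the intra-individual
#' (repetition) and inter-individual (animal) factors, and the minimum
#' detectable change at a medium effect size (Cohen's d = 0.5), in cells/uL
#' and as a percentage. Useful for planning sample sizes for the 42
#' peripheral-blood subsets without running a pilot.
#'
#' @return A list of two data frames: `eta` (`panel`, `variable`,
#'   `eta_intra_pct`, `eta_inter_pct`) and `mdc` (`panel`, `variable`,
#'   `mdc_cells`, `mdc_relative_pct`).
#' @export
reference_variability <- function() {
  dir <- system.file("extdata", "reference", package = "cytovar",
                     mustWork = TRUE)
  list(eta = utils::read.csv(file.path(dir, "healthy_eta_shares.csv"),
                             stringsAsFactors = FALSE),
       mdc = utils::read.csv(file.path(dir, "detectable_change.csv"),
                             stringsAsFactors = FALSE))
}
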