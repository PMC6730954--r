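# Shipped reference data.

#' Reference regression coefficients at pleiotropic loci
#'
#' Coefficient estimates reported for the pleiotropic QTL of two
#' wild-derived house-mouse F2 intercrosses (a cross between subspecies,
#' `cast_x_musc`, and one within subspecies, `dom_x_dom`), as printed in the
#' source mapping study: unmediated and mediated additive effects on mean
#' SC length and mean MLH1 count (`beta_sc`, `beta_prime_sc`, `beta_co`,
#' `beta_prime_co`), mediator coefficients (`alpha_sc`, `alpha_co`), Sobel
#' statistics and p-values. Each locus appears twice, evaluated at the
#' peak-LOD position of the SC-length QTL (`eval_peak = "sc"`) and of the
#' MLH1 QTL (`eval_peak = "co"`).
#'
#' Useful as a worked example for [proportion_mediated()] and
#' [sobel_test()]: e.g. the proportion of the chromosome-4 effect on SC
#' length mediated by crossover count is `(3.73 - 2.96) / 3.73 = 0.21`.
#'
#' @return Data frame, one row per locus and evaluation position.
#' @export
pleiotropic_loci_coefficients <- function() {
  path <- system.file("extdata", "pleiotropic_loci_coefficients.tsv",
                      package = "scmeio", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chr = "character"))
}
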