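# ---------------------------------------------------------------------------
# Bundled example tables from a national-scale (Wales, 2015 -> 2030) LULC
# projection exercise: the driver screening table, the published 2030
# transition probability matrices under the business-as-usual and
# ecosystem-conservation scenarios, and the conservation-scenario edit file.
# These are printed (3-decimal) values, usable as pipeline inputs; the
# underlying national rasters are not distributed.
# ---------------------------------------------------------------------------

wales_extdata <- function(file) {
  system.file("extdata", file, package = "landmarkov", mustWork = TRUE)
}

#' Bundled Wales example inputs
#'
#' `wales_screening_table()` returns the 20-variable driver screening table
#' (name, Cramer's V against observed change, static/dynamic type).
#' `wales_transition_matrix()` returns the published 2030 transition
#' probability matrix of the requested scenario as a
#' `TransitionProbabilityMatrix` (rows sum to 1 only within printed-rounding
#' tolerance). `wales_ec_scenario()` returns the conservation-scenario edit
#' list; `wales_legend()` the six-class legend.
#'
#' @param scenario `"bau"` (business as usual) or `"ec"` (ecosystem
#'   conservation).
#' @return see above.
#' @export
wales_screening_table <- function() {
  read.csv(wales_extdata("wales_cramers_v.csv"), stringsAsFactors = FALSE)
}

#' @rdname wales_screening_table
#' @export
wales_legend <- function() read_legend(wales_extdata("wales_legend.csv"))

#' @rdname wales_screening_table
#' @export
wales_transition_matrix <- function(scenario = c("bau", "ec")) {
  scenario <- match.arg(scenario)
  P <- read_matrix_csv(wales_extdata(sprintf("wales_%s_2030.csv", scenario)))
  new_tpm(P, horizon_years = 15, legend = wales_legend())
}

#' @rdname wales_screening_table
#' @export
wales_ec_scenario <- function() read_scenario(wales_extdata("wales_ec.scn"))
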