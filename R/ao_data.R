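#' Bundled oxygen-uptake rate data for antioxidants AO1 and AO2
#'
#' Initial oxidation rates of AIBN-initiated 1,4-dioxane oxidation at 348 K
#' (`Vi = 1e-7` mol L^-1 s^-1) at increasing inhibitor concentrations, for
#' the two chromane-derived antioxidants studied experimentally. The zero
#' concentration row is the uninhibited rate V0. Concentrations and rates are
#' in mol/L and mol L^-1 s^-1.
#'
#' @param id `"AO1"` or `"AO2"`.
#' @return A [rate_table()].
#' @examples
#' fit_fk7(ao_rate_table("AO1"))
#' @export
ao_rate_table <- function(id = c("AO1", "AO2")) {
  id <- match.arg(id)
  path <- system.file("extdata", paste0(tolower(id), "_rates.csv"),
                      package = "oxiqspr", mustWork = TRUE)
  read_rate_table(path, id = id)
}

#' Reference experimental quantities for AO1 and AO2
#'
#' Published companion values used as inputs to the kinetic bookkeeping:
#' stoichiometric inhibition coefficients (`f`, with SE) from the
#' induction-period analysis, the reported effective constants `fk7` (with
#' SE), and the consensus-model predictions of log10(k7) for both compounds.
#' The training-set activity range of the published models (7.057 log-units)
#' is included for threshold arithmetic.
#'
#' @return Nested list with elements `AO1`, `AO2` (each: `f`, `f_se`, `fk7`,
#'   `fk7_se`, `pred_logk7` named by model M1..M6) and `train_range`.
#' @export
ao_reference <- function() {
  list(
    AO1 = list(f = 30, f_se = 4, fk7 = 1.32e6, fk7_se = 0.3e6,
               pred_logk7 = c(M1 = 5.21, M2 = 4.79, M3 = 5.17,
                              M4 = 5.25, M5 = 5.07, M6 = 5.19)),
    AO2 = list(f = 40, f_se = 2, fk7 = 1.08e6, fk7_se = 0.2e6,
               pred_logk7 = c(M1 = 5.10, M2 = 5.32, M3 = 5.21,
                              M4 = 5.23, M5 = 5.20, M6 = 5.15)),
    train_range = 7.057
  )
}
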