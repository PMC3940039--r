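# Population -> free-energy conversions for two-state conformational
# equilibria.

.R_GAS <- 8.314  # J mol^-1 K^-1

#' A two-state population pair
#'
#' @param p Population of the tracked state (for a cis/trans peptide
#'   equilibrium, conventionally the cis state), in `(0, 1)`; the other state
#'   has `1 - p`.  Note that the tracked state need not be the less populated
#'   one (a variant can invert the equilibrium).
#' @param temperature Temperature in K, default 298.15.
#' @return A `population_pair` list.
#' @export
population_pair <- function(p, temperature = 298.15) {
  if (p <= 0 || p >= 1) stopf("population must lie strictly in (0, 1)")
  if (temperature <= 0) stopf("temperature must be positive")
  structure(list(p = p, temperature = temperature), class = "population_pair")
}

#' Free-energy difference from a two-state population
#'
#' \eqn{\Delta G = -R T \ln(p / (1 - p))} in kJ/mol: positive when the
#' tracked state is the higher-free-energy (less populated) one.
#'
#' @param pair A `population_pair`, or a bare population in `(0, 1)`.
#' @param temperature Temperature in K (ignored when `pair` is a
#'   `population_pair`).
#' @return Delta G in kJ/mol.
#' @export
delta_g <- function(pair, temperature = 298.15) {
  if (!inherits(pair, "population_pair")) pair <- population_pair(pair, temperature)
  -.R_GAS * pair$temperature * log(pair$p / (1 - pair$p)) / 1000
}

#' Free-energy shift between two equilibria
#'
#' \eqn{\Delta\Delta G = \Delta G_1 - \Delta G_2} at a shared temperature;
#' antisymmetric under argument exchange.
#'
#' @param pair_1,pair_2 `population_pair` objects (or bare populations,
#'   interpreted at `temperature`).
#' @param temperature Temperature in K for bare-population input.
#' @return Delta Delta G in kJ/mol.
#' @export
delta_delta_g <- function(pair_1, pair_2, temperature = 298.15) {
  if (!inherits(pair_1, "population_pair")) pair_1 <- population_pair(pair_1, temperature)
  if (!inherits(pair_2, "population_pair")) pair_2 <- population_pair(pair_2, temperature)
  if (abs(pair_1$temperature - pair_2$temperature) > 1e-9)
    stopf("configuration error: temperatures differ (%.2f K vs %.2f K)",
          pair_1$temperature, pair_2$temperature)
  delta_g(pair_1) - delta_g(pair_2)
}
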