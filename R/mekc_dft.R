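#' MEKC retention factor from migration times
#'
#' Retention factor of an analyte in micellar electrokinetic chromatography
#' from its migration time and those of the electroosmotic-flow and micelle
#' markers: `k = (tR - tEOF) / (tEOF (1 - tR / tMC))`, returned as
#' `log10(k)`. Valid analytes migrate strictly between the two markers;
#' `tR <= tEOF` (no micellar partitioning, `k <= 0`) and `tR >= tMC` (fully
#' micellized) are domain errors.
#'
#' @param tR Analyte migration time(s) (min).
#' @param tEOF EOF-marker migration time (min, > 0).
#' @param tMC Micelle-marker migration time (min, > tEOF).
#' @return `log10` retention factor(s).
#' @examples
#' terabe_logk(4, tEOF = 2, tMC = 10)
#' @export
terabe_logk <- function(tR, tEOF, tMC) {
  n <- max(length(tR), length(tEOF), length(tMC))
  tR <- rep_len(tR, n); tEOF <- rep_len(tEOF, n); tMC <- rep_len(tMC, n)
  if (any(tEOF <= 0) || any(tMC <= tEOF)) {
    abort("need 0 < tEOF < tMC")
  }
  if (any(tR <= tEOF)) abort("tR <= tEOF: retention factor is not positive")
  if (any(tR >= tMC)) abort("tR >= tMC: analyte fully micellized")
  k <- (tR - tEOF) / (tEOF * (1 - tR / tMC))
  log10(k)
}

# gas constant per energy unit, in <unit>/ (mol K)
.gas_constant <- c("kcal/mol" = 1.987204259e-3, "kJ/mol" = 8.31446262e-3)

#' logP from DFT solvation free energies
#'
#' Converts Gibbs free energies of the solvated species in water and
#' n-octanol into a partition coefficient:
#' `logP = (G_water - G_octanol) / (2.303 R T)`. A positive difference
#' (solute better solvated in octanol) gives a positive logP. Both
#' energies must share the declared unit.
#'
#' @param g_water,g_octanol Gibbs free energies of the solute in each
#'   phase; vectorized.
#' @param unit `"kcal/mol"` or `"kJ/mol"`.
#' @param temperature Absolute temperature (K); default 298.15.
#' @return logP value(s) (dimensionless, log10 units).
#' @examples
#' dft_logp(0, -1.3645, unit = "kcal/mol") # ~1
#' @export
dft_logp <- function(g_water, g_octanol, unit = c("kcal/mol", "kJ/mol"),
                     temperature = 298.15) {
  unit <- match.arg(unit)
  if (temperature <= 0) abort("temperature must be positive (K)")
  R <- .gas_constant[[unit]]
  (g_water - g_octanol) / (2.303 * R * temperature)
}
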