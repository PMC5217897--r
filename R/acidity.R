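#' Moisture-corrected total titratable acidity
#'
#' Total titratable acidity of gari expressed as percent lactic acid
#' (g per 100 g, dry-corrected):
#' `TTA% = 0.450 x titration volume [mL] / (1 - h)`,
#' where the titration volume is the 0.05 M sodium hydroxide consumed to the
#' phenolphthalein endpoint for a 20.0 mL aliquot of a 5.00 g / 100.0 mL
#' aqueous extract, and `h` is the sample's moisture fraction. The factor
#' 0.450 bundles the protocol stoichiometry (it equals
#' `0.05 mmol/mL x (100/20) x 90.08 mg/mmol / 5000 mg x 100` up to rounding)
#' and is kept as the literal protocol constant; dividing by `1 - h` refers
#' the result to dry matter. Only lactic-acid equivalents are reported, as
#' lactic is the dominant acid in gari.
#'
#' @param titration_volume_ml NaOH volume to endpoint, mL. Vectorised.
#' @param moisture_fraction Moisture fraction `h` in `[0, 1)`, typically the
#'   per-sample mean from [moisture_content()]. Vectorised.
#' @return Percent lactic acid on a dry-corrected basis.
#' @export
#' @examples
#' corrected_tta(1.00, 0)    # 0.450
#' corrected_tta(2.00, 0.10) # 1.000
corrected_tta <- function(titration_volume_ml, moisture_fraction) {
  if (any(!is.finite(titration_volume_ml)) || any(titration_volume_ml < 0)) {
    stop("Titration volume must be non-negative.")
  }
  if (any(!is.finite(moisture_fraction)) || any(moisture_fraction < 0) ||
      any(moisture_fraction >= 1)) {
    stop("Moisture fraction must lie in [0, 1).")
  }
  0.450 * titration_volume_ml / (1 - moisture_fraction)
}
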