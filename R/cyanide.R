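#' Total cyanide from picrate-paper photometry
#'
#' Converts the absorbance at 510 nm of the eluted picrate strip into total
#' cyanide in ppm: `ppm = absorbance x 396`. The factor 396 presumes the
#' kit's nominal geometry of 100 mg sample in 5.0 mL elution water;
#' off-nominal readings are flagged with a warning and can optionally be
#' rescaled proportionally (`factor x (100/mass_mg) x (volume_ml/5)`), the
#' only dimensionally consistent extension of the fixed-geometry factor.
#'
#' @param absorbance_510nm Extinction at 510 nm, dimensionless. Vectorised.
#' @param sample_mass_mg Sample mass, mg (kit nominal 100 mg).
#' @param elution_volume_ml Elution water volume, mL (kit nominal 5.0 mL).
#' @param rescale If `TRUE`, rescale the conversion factor for off-nominal
#'   geometry instead of only warning.
#' @return Total cyanide in ppm.
#' @export
#' @examples
#' cyanide_ppm(1.00) # 396 ppm
cyanide_ppm <- function(absorbance_510nm, sample_mass_mg = 100,
                        elution_volume_ml = 5.0, rescale = FALSE) {
  if (any(!is.finite(absorbance_510nm)) || any(absorbance_510nm < 0)) {
    stop("Instrument error: absorbance must be non-negative.")
  }
  if (any(sample_mass_mg <= 0) || any(elution_volume_ml <= 0)) {
    stop("Sample mass and elution volume must be positive.")
  }
  factor <- 396
  off_nominal <- any(sample_mass_mg != 100) || any(elution_volume_ml != 5.0)
  if (off_nominal) {
    if (rescale) {
      factor <- factor * (100 / sample_mass_mg) * (elution_volume_ml / 5.0)
    } else {
      warning("Off-nominal kit geometry (nominal: 100 mg / 5.0 mL); ",
              "conversion factor 396 applied unscaled. ",
              "Use `rescale = TRUE` for a proportional correction.")
    }
  }
  absorbance_510nm * factor
}

#' Picrate colour chart
#'
#' The kit's chart of 10 colour shades spanning 0 to 800 ppm total cyanide.
#' The per-shade ppm values are not standardised, so they are configurable;
#' the default anchors the 10 shades evenly over 0-800 ppm.
#'
#' @param shade_levels_ppm Strictly increasing vector of 10 shade values,
#'   starting at 0 and ending at 800.
#' @return A `color_chart` object (numeric vector of shade levels).
#' @export
color_chart <- function(shade_levels_ppm = seq(0, 800, length.out = 10)) {
  x <- as.numeric(shade_levels_ppm)
  if (length(x) != 10 || anyNA(x)) {
    stop("A colour chart has exactly 10 shade levels.")
  }
  if (is.unsorted(x, strictly = TRUE) || x[1] != 0 || x[10] != 800) {
    stop("Shade levels must increase strictly from 0 to 800 ppm.")
  }
  structure(x, class = "color_chart")
}

#' Semi-quantitative chart classification
#'
#' Assigns a cyanide concentration to the nearest chart shade; a value
#' exactly midway between two shades is assigned to the lower one. Chart
#' comparison is only a rough criticality screen next to the photometric
#' value.
#'
#' @param ppm Total cyanide in ppm, non-negative. Vectorised.
#' @param chart A [color_chart()].
#' @return The nearest shade level(s), in ppm.
#' @export
chart_class <- function(ppm, chart = color_chart()) {
  stopifnot(inherits(chart, "color_chart"))
  if (any(!is.finite(ppm)) || any(ppm < 0)) {
    stop("Cyanide concentration must be non-negative.")
  }
  vapply(ppm, function(p) {
    d <- abs(as.numeric(chart) - p)
    # which.min takes the first (lower) level on ties
    as.numeric(chart)[which.min(d)]
  }, numeric(1))
}
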