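#' Tapped bulk density
#'
#' Mass of the sample divided by its tapped bulk volume (cylinder tapped 40
#' times before the volume is read).
#'
#' @param sample_mass_g Sample mass in g. Vectorised.
#' @param tapped_volume_cm3 Tapped volume in cm^3. Vectorised.
#' @return Bulk density in g/cm^3.
#' @export
#' @examples
#' bulk_density(10, 16) # 0.625 g/cm^3
bulk_density <- function(sample_mass_g, tapped_volume_cm3) {
  if (any(!is.finite(sample_mass_g)) || any(sample_mass_g <= 0)) {
    stop("Degenerate reading: sample mass must be positive.")
  }
  if (any(!is.finite(tapped_volume_cm3)) || any(tapped_volume_cm3 <= 0)) {
    stop("Degenerate reading: tapped volume must be positive.")
  }
  sample_mass_g / tapped_volume_cm3
}

#' Swelling index
#'
#' Ratio of the swollen volume (after 4 h of soaking in distilled water) to
#' the initial bulk volume. Gari typically swells three- to four-fold; a
#' value below 1 is physically possible for a compacting sample and is
#' accepted with a warning.
#'
#' @param initial_volume_ml Initial bulk volume in mL. Vectorised.
#' @param swollen_volume_ml Swollen volume in mL. Vectorised.
#' @return Dimensionless swelling index.
#' @export
#' @examples
#' swelling_index(15, 52.5) # 3.5
swelling_index <- function(initial_volume_ml, swollen_volume_ml) {
  if (any(!is.finite(initial_volume_ml)) || any(initial_volume_ml <= 0)) {
    stop("Degenerate reading: initial volume must be positive.")
  }
  if (any(!is.finite(swollen_volume_ml)) || any(swollen_volume_ml <= 0)) {
    stop("Degenerate reading: swollen volume must be positive.")
  }
  si <- swollen_volume_ml / initial_volume_ml
  if (any(si < 1)) {
    warning("Swelling index below 1: sample volume decreased on soaking.")
  }
  si
}

#' Thermogravimetric moisture content
#'
#' Fractional drying loss after oven drying (105 degrees C, 48 h):
#' `(fwt - dwt) / fwt`, where `fwt` is the fresh and `dwt` the dry weight.
#' This is the drying-loss reading consistent with gari's reported moisture
#' range of a few percent; the literal dry-to-fresh ratio `dwt/fwt` is
#' available via `as_printed = TRUE` for traceability against sources that
#' tabulate the ratio itself.
#'
#' An optional intermediate weighing after 24 h supports a drying-adequacy
#' check: if the 24 h and final masses differ by more than
#' `drying_tolerance` (relative), the reading is flagged with a warning but
#' not rejected.
#'
#' @param fresh_weight_g Fresh weight in g. Vectorised.
#' @param dry_weight_g Dry (48 h) weight in g. Vectorised.
#' @param mass_24h_g Optional mass after 24 h of drying, in g.
#' @param drying_tolerance Maximum relative difference between the 24 h and
#'   48 h masses before the reading is flagged (default 0.001, i.e. 0.1%).
#' @param as_printed If `TRUE`, return the ratio `dwt/fwt` instead of the
#'   drying loss.
#' @return Moisture content as a fraction in `[0, 1)`.
#' @export
#' @examples
#' moisture_content(10, 9.2) # 0.08
moisture_content <- function(fresh_weight_g, dry_weight_g, mass_24h_g = NULL,
                             drying_tolerance = 0.001, as_printed = FALSE) {
  if (any(!is.finite(fresh_weight_g)) || any(fresh_weight_g <= 0)) {
    stop("Degenerate reading: fresh weight must be positive.")
  }
  if (any(!is.finite(dry_weight_g)) || any(dry_weight_g <= 0)) {
    stop("Degenerate reading: dry weight must be positive.")
  }
  if (any(dry_weight_g > fresh_weight_g)) {
    stop("Inconsistent reading: dry weight exceeds fresh weight ",
         "(sample gained mass on drying).")
  }
  if (!is.null(mass_24h_g)) {
    rel <- abs(mass_24h_g - dry_weight_g) / dry_weight_g
    if (any(rel > drying_tolerance, na.rm = TRUE)) {
      warning("Drying may be incomplete: mass still changing after 24 h ",
              "beyond the ", format(100 * drying_tolerance), "% tolerance.")
    }
  }
  if (as_printed) {
    dry_weight_g / fresh_weight_g
  } else {
    (fresh_weight_g - dry_weight_g) / fresh_weight_g
  }
}
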