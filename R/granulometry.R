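#' Sieve-stack specification
#'
#' Defines the size classes of a dry-sieving stack. Each sieve aperture is the
#' lower bound of the class retained on that sieve; the pan (material passing
#' the finest sieve) forms the lowest class and the material retained on the
#' coarsest sieve forms an open-topped class that is closed at
#' `top_upper_bound_um`.
#'
#' The default apertures are the nine-sieve Retsch series used for gari
#' analysis (125 to 2000 um). The pan class is bounded below at 0 um because
#' particle diameters are physically non-negative, and the oversize class is
#' closed at 1.4 x the largest aperture, continuing the approximately sqrt(2)
#' progression of the sieve series; both bounds are configurable.
#'
#' @param mesh_sizes_um Sieve apertures in micrometres, strictly increasing.
#' @param pan_lower_bound_um Lower diameter bound assigned to the pan class.
#' @param top_upper_bound_um Upper diameter bound assigned to the oversize
#'   class; must exceed the largest aperture.
#'
#' @return An object of class `sieve_spec`: a list with the apertures, the
#'   two closing bounds, and a `classes` tibble of `(lower_um, upper_um)`
#'   rows ordered by increasing diameter (pan first).
#' @export
#' @examples
#' spec <- sieve_spec()
#' spec$classes
sieve_spec <- function(mesh_sizes_um = c(125, 180, 250, 355, 500, 710,
                                         1000, 1400, 2000),
                       pan_lower_bound_um = 0,
                       top_upper_bound_um = 1.4 * max(mesh_sizes_um)) {
  mesh_sizes_um <- as.numeric(mesh_sizes_um)
  if (length(mesh_sizes_um) < 1 || anyNA(mesh_sizes_um)) {
    stop("`mesh_sizes_um` must be a non-empty numeric vector without NA.")
  }
  if (any(mesh_sizes_um <= 0)) {
    stop("All sieve apertures must be positive.")
  }
  if (is.unsorted(mesh_sizes_um, strictly = TRUE)) {
    stop("`mesh_sizes_um` must be strictly increasing.")
  }
  if (pan_lower_bound_um < 0 || pan_lower_bound_um >= min(mesh_sizes_um)) {
    stop("`pan_lower_bound_um` must lie in [0, smallest aperture).")
  }
  if (top_upper_bound_um <= max(mesh_sizes_um)) {
    stop("`top_upper_bound_um` must exceed the largest aperture.")
  }
  lower <- c(pan_lower_bound_um, mesh_sizes_um)
  upper <- c(mesh_sizes_um, top_upper_bound_um)
  structure(
    list(
      mesh_sizes_um = mesh_sizes_um,
      pan_lower_bound_um = pan_lower_bound_um,
      top_upper_bound_um = top_upper_bound_um,
      classes = tibble::tibble(lower_um = lower, upper_um = upper)
    ),
    class = "sieve_spec"
  )
}

#' @export
print.sieve_spec <- function(x, ...) {
  cat("Sieve-stack specification:", length(x$mesh_sizes_um), "sieves + pan\n")
  cat("  apertures [um]:", paste(x$mesh_sizes_um, collapse = ", "), "\n")
  cat("  pan class: (", x$pan_lower_bound_um, ",", min(x$mesh_sizes_um),
      "]   oversize class: (", max(x$mesh_sizes_um), ",",
      x$top_upper_bound_um, "]\n")
  invisible(x)
}

#' Mass-fraction size distribution from one sieving trial
#'
#' Converts the retained masses of one sieve-stack run into mass fractions
#' per size class and the cumulative undersize curve.
#'
#' @param retained_mass_g Retained mass in grams per class, ordered by
#'   increasing diameter: pan first, then each sieve up to the coarsest.
#'   Length must equal the number of classes of `spec` (sieves + 1).
#' @param spec A [sieve_spec()].
#'
#' @return An object of class `size_distribution`: a tibble with columns
#'   `lower_um`, `upper_um`, `mass_fraction` and `cumulative` (running sum of
#'   mass fractions by increasing diameter, ending at 1).
#' @export
#' @examples
#' spec <- sieve_spec()
#' d <- mass_fractions(c(2, 6, 10, 16, 22, 20, 14, 6, 3, 1), spec)
#' weighted_mean_diameter(d)
#' median_diameter(d)
mass_fractions <- function(retained_mass_g, spec) {
  stopifnot(inherits(spec, "sieve_spec"))
  m <- as.numeric(retained_mass_g)
  n_class <- nrow(spec$classes)
  if (length(m) != n_class) {
    stop("Schema mismatch: expected ", n_class, " retained masses (pan + ",
         n_class - 1L, " sieves), got ", length(m), ".")
  }
  if (anyNA(m) || any(m < 0)) {
    stop("Retained masses must be non-negative and non-missing.")
  }
  total <- sum(m)
  if (total <= 0) {
    stop("Degenerate trial: total retained mass must be positive.")
  }
  frac <- m / total
  out <- tibble::tibble(
    lower_um = spec$classes$lower_um,
    upper_um = spec$classes$upper_um,
    mass_fraction = frac,
    cumulative = cumsum(frac)
  )
  class(out) <- c("size_distribution", class(out))
  out
}

validate_size_distribution <- function(dist) {
  if (!inherits(dist, "size_distribution")) {
    stop("Expected a `size_distribution` (see `mass_fractions()`).")
  }
  if (abs(sum(dist$mass_fraction) - 1) > 1e-9) {
    stop("Internal invariant violated: mass fractions must sum to 1.")
  }
  invisible(dist)
}

#' Median diameter from the cumulative undersize curve
#'
#' The median is the diameter at which the cumulative mass distribution
#' crosses 50%. The cumulative curve is taken piecewise-linear through the
#' points (class upper bound, cumulative fraction), anchored on the left at
#' (pan lower bound, 0), mirroring the graphical read-off on a cumulative
#' distribution plot.
#'
#' @param dist A `size_distribution` from [mass_fractions()].
#' @return Median diameter in micrometres.
#' @export
median_diameter <- function(dist) {
  validate_size_distribution(dist)
  x <- c(dist$lower_um[1], dist$upper_um)
  y <- c(0, dist$cumulative)
  i <- which(y >= 0.5)[1]
  if (is.na(i)) {
    stop("Internal invariant violated: cumulative curve never reaches 0.5.")
  }
  if (i == 1L) return(x[1])
  # linear interpolation inside the class containing the crossing
  x[i - 1] + (0.5 - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
}

#' Mass-weighted mean diameter
#'
#' The weighted mean diameter of the distribution,
#' \eqn{\bar{x}_3 = \sum_i \frac{d_{i-1} + d_i}{2}\,\mu_{3,i}}, i.e. the
#' mass-fraction-weighted average of the class midpoint diameters over all
#' classes including pan and oversize.
#'
#' @inheritParams median_diameter
#' @return Weighted mean diameter in micrometres.
#' @export
weighted_mean_diameter <- function(dist) {
  validate_size_distribution(dist)
  sum((dist$lower_um + dist$upper_um) / 2 * dist$mass_fraction)
}

#' Replicate mean and sample standard deviation
#'
#' Arithmetic average over measurement replicates, as reported per sample,
#' with the sample (n-1) standard deviation. For a single replicate the SD is
#' reported as `NA`.
#'
#' @param values Numeric vector of replicate results (length >= 1).
#' @return A list with elements `mean`, `sd` (`NA` for n = 1) and `n`.
#' @export
#' @examples
#' average_over_trials(c(573, 561, 574, 592))
average_over_trials <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop("Degenerate input: at least one replicate value is required.")
  }
  list(
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else NA_real_,
    n = length(values)
  )
}
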