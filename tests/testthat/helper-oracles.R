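# Independent brute-force oracles used to freeze expected values.

# term-by-term weighted mean: explicit loop over classes
oracle_weighted_mean <- function(lower, upper, frac) {
  s <- 0
  for (i in seq_along(frac)) {
    s <- s + (lower[i] + upper[i]) / 2 * frac[i]
  }
  s
}

# median by dense inversion of the same piecewise-linear cumulative curve
oracle_median_finegrid <- function(lower, upper, cumulative) {
  x <- c(lower[1], upper)
  y <- c(0, cumulative)
  f <- function(d) stats::approx(x, y, xout = d, ties = "ordered")$y - 0.5
  stats::uniroot(f, interval = range(x), tol = 1e-9)$root
}

# two-pass mean / sample SD
oracle_mean_sd <- function(v) {
  m <- sum(v) / length(v)
  list(mean = m, sd = sqrt(sum((v - m)^2) / (length(v) - 1)))
}

# first-principles TTA coefficient from the titration protocol:
# molarity [mmol/mL] x aliquot-to-extract scale-up x molar mass [mg/mmol],
# per sample mass, as percent
oracle_tta_coefficient <- function(naoh_molarity = 0.05,
                                   extract_volume_ml = 100,
                                   aliquot_ml = 20,
                                   sample_mass_g = 5,
                                   lactic_molar_mass = 90.08) {
  mmol_per_ml_titrant <- naoh_molarity
  scale_up <- extract_volume_ml / aliquot_ml
  mg_lactic_per_ml_titrant <- mmol_per_ml_titrant * scale_up * lactic_molar_mass
  100 * mg_lactic_per_ml_titrant / (sample_mass_g * 1000)
}

# random valid sieve trial (retained masses) for property sweeps
random_retained_masses <- function(spec, total = 100) {
  n <- nrow(spec$classes)
  m <- stats::runif(n)
  m * total / sum(m)
}
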