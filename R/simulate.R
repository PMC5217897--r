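#' Declared ground truth for one synthetic sample
#'
#' Holds the true quality parameters from which raw instrument readings are
#' generated. Bounds are broad physical-plausibility checks spanning the
#' range observed for market gari (e.g. gross calorific value near
#' 15-16 kJ/g, bulk density 0.3-1.0 g/cm^3, moisture below 30%).
#'
#' The grain-size truth is a mass-weighted lognormal: `median_um` is the
#' distribution median, `sigma_ln` its log-scale standard deviation, so the
#' mass-weighted mean diameter of the underlying continuous distribution is
#' `median_um * exp(sigma_ln^2 / 2)`.
#'
#' @param sample_id Sample label.
#' @param median_um True median grain diameter, um.
#' @param sigma_ln Lognormal shape (log-scale SD), > 0.
#' @param bulk_density_g_cm3 True tapped bulk density, g/cm^3.
#' @param swelling_index True swelling index (dimensionless).
#' @param moisture_fraction True moisture fraction in `[0, 0.3)`.
#' @param gcv_kJ_g True gross calorific value, kJ/g.
#' @param cyanide_ppm True total cyanide, ppm.
#' @param tta_percent True dry-corrected acidity, percent lactic acid.
#' @return A one-row tibble of class `sample_truth`.
#' @export
sample_truth <- function(sample_id, median_um, sigma_ln = 0.45,
                         bulk_density_g_cm3, swelling_index,
                         moisture_fraction, gcv_kJ_g = 15.6,
                         cyanide_ppm, tta_percent) {
  chk <- function(x, lo, hi, what) {
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
      stop("Truth out of plausible bounds: ", what, " must lie in [",
           lo, ", ", hi, "].")
    }
  }
  chk(median_um, 100, 2500, "median_um")
  if (any(sigma_ln <= 0)) stop("Truth out of plausible bounds: sigma_ln must be positive.")
  chk(sigma_ln, 1e-9, 2, "sigma_ln")
  chk(bulk_density_g_cm3, 0.3, 1.0, "bulk_density_g_cm3")
  chk(swelling_index, 1, 6, "swelling_index")
  chk(moisture_fraction, 0, 0.3, "moisture_fraction")
  chk(gcv_kJ_g, 10, 30, "gcv_kJ_g")
  chk(cyanide_ppm, 0, 800, "cyanide_ppm")
  chk(tta_percent, 0, 5, "tta_percent")
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    median_um = median_um, sigma_ln = sigma_ln,
    bulk_density_g_cm3 = bulk_density_g_cm3,
    swelling_index = swelling_index,
    moisture_fraction = moisture_fraction,
    gcv_kJ_g = gcv_kJ_g,
    cyanide_ppm = cyanide_ppm,
    tta_percent = tta_percent
  )
  class(out) <- c("sample_truth", class(out))
  out
}

#' Raw-scale measurement-noise defaults
#'
#' Gaussian noise standard deviations applied on the raw instrument scale
#' (masses, volumes, temperatures, absorbances), truncated at physical
#' bounds. Defaults are anchored to the accuracies of the instruments used
#' for gari analysis: a 0.01 g technical balance for sieve fractions and
#' oven weighings, graduated cylinders read to a few tenths of a mL, a
#' burette accurate to 0.01 mL (operator endpoint detection dominates), a
#' temperature sensor resolving ~0.02 K point-to-point, and photometric
#' repeatability of a few thousandths of an absorbance unit.
#'
#' @param sieve_mass_sd_g SD of each retained class mass, g.
#' @param volume_sd_cm3 SD of the tapped-volume reading, cm^3.
#' @param swell_volume_sd_ml SD of each soaking-cylinder volume reading, mL.
#' @param fresh_sd_g,dry_sd_g SD of the fresh and dry weighings, g.
#' @param absorbance_sd SD of the 510 nm absorbance reading.
#' @param titration_sd_ml SD of the endpoint titration volume, mL.
#' @param trace_sd_K SD of each temperature-trace point, K.
#' @return A named list of noise parameters.
#' @export
assay_noise <- function(sieve_mass_sd_g = 0.5,
                        volume_sd_cm3 = 0.2,
                        swell_volume_sd_ml = 0.3,
                        fresh_sd_g = 0.01,
                        dry_sd_g = 0.02,
                        absorbance_sd = 0.0025,
                        titration_sd_ml = 0.02,
                        trace_sd_K = 0.02) {
  ns <- list(sieve_mass_sd_g = sieve_mass_sd_g,
             volume_sd_cm3 = volume_sd_cm3,
             swell_volume_sd_ml = swell_volume_sd_ml,
             fresh_sd_g = fresh_sd_g, dry_sd_g = dry_sd_g,
             absorbance_sd = absorbance_sd,
             titration_sd_ml = titration_sd_ml,
             trace_sd_K = trace_sd_K)
  if (any(unlist(ns) < 0)) stop("Noise standard deviations must be >= 0.")
  ns
}

#' Simulate one sieve-stack trial
#'
#' Discretises the sample's mass-weighted lognormal size distribution onto
#' the sieve classes, scales to the charged mass, perturbs each class mass
#' with Gaussian noise truncated at zero, and renormalises to the total
#' (sieving conserves mass).
#'
#' @param truth A [sample_truth()] row.
#' @param spec A [sieve_spec()].
#' @param total_mass_g Charged sample mass, g.
#' @param noise_sd_g Per-class mass noise SD, g.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of retained masses (pan first), summing to
#'   `total_mass_g`, ready for [mass_fractions()].
#' @export
simulate_sieve_trial <- function(truth, spec = sieve_spec(),
                                 total_mass_g = 100,
                                 noise_sd_g = assay_noise()$sieve_mass_sd_g,
                                 seed = NULL) {
  stopifnot(inherits(spec, "sieve_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (truth$sigma_ln <= 0) stop("sigma_ln must be positive.")
  mu <- log(truth$median_um)
  p <- stats::plnorm(spec$classes$upper_um, mu, truth$sigma_ln) -
    stats::plnorm(spec$classes$lower_um, mu, truth$sigma_ln)
  if (sum(p) <= 0) stop("Degenerate truth: no mass falls inside the stack.")
  p <- p / sum(p) # fold the tail beyond the oversize bound back in
  m <- p * total_mass_g
  m <- pmax(m + stats::rnorm(length(m), 0, noise_sd_g), 0)
  m * total_mass_g / sum(m)
}

#' Simulate a bomb-calorimeter firing
#'
#' Inverts the reduction chain: the temperature rise implied by the declared
#' calorific values, masses and calorimeter constant is computed exactly,
#' then a realistic trace is synthesised with linear drift in the fore and
#' after periods, an exponential approach to the post-ignition plateau, and
#' Gaussian temperature noise.
#'
#' @param kind `"sample"` or `"calibration"`.
#' @param cfg A [calorimeter_config()].
#' @param K_J_per_K True calorimeter constant, J/K.
#' @param gcv_sample_J_per_g True sample gross calorific value, J/g
#'   (sample runs).
#' @param sample_mass_g,fuel_mass_g Sample and spiking-fuel masses, g
#'   (sample runs).
#' @param benzoic_mass_g,benzoic_gcv_J_per_g Pellet mass and certified
#'   calorific value (calibration runs).
#' @param t_end_s,dt_s,ignition_time_s,tau_s Trace timing: total duration,
#'   sampling interval, firing time and exponential time constant, s.
#' @param T0_K Starting bath temperature, K.
#' @param drift_K_per_s Linear drift of the bath, K/s (applied to both
#'   periods).
#' @param noise_sd_K Per-point temperature noise SD, K.
#' @param seed Optional integer seed.
#' @return A list with `times_s`, `temps_K`, `ignition_time_s`, the masses,
#'   `kind` and the exact implied `delta_T_true_K`.
#' @export
simulate_calorimeter_run <- function(kind = c("sample", "calibration"),
                                     cfg = calorimeter_config(),
                                     K_J_per_K = 450,
                                     gcv_sample_J_per_g = 15600,
                                     sample_mass_g = 0.320,
                                     fuel_mass_g = 0.080,
                                     benzoic_mass_g = 1.000,
                                     benzoic_gcv_J_per_g = 26460,
                                     t_end_s = 1800, dt_s = 2,
                                     ignition_time_s = 600, tau_s = 45,
                                     T0_K = 298.15,
                                     drift_K_per_s = 1e-5,
                                     noise_sd_K = assay_noise()$trace_sd_K,
                                     seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "calorimeter_config"))
  if (!is.null(seed)) set.seed(seed)
  energy_J <- if (kind == "sample") {
    gcv_sample_J_per_g * sample_mass_g +
      cfg$fuel_gcv_J_per_g * fuel_mass_g +
      cfg$wire_gcv_J_per_g * cfg$wire_mass_g
  } else {
    benzoic_gcv_J_per_g * benzoic_mass_g +
      cfg$wire_gcv_J_per_g * cfg$wire_mass_g
  }
  dT <- energy_J /
    (cfg$water_mass_g * cfg$water_heat_capacity_J_per_gK + K_J_per_K)
  if (dT <= 0) stop("Inconsistent truth: implied temperature rise is not positive.")
  times <- seq(0, t_end_s, by = dt_s)
  rise <- ifelse(times > ignition_time_s,
                 dT * (1 - exp(-(times - ignition_time_s) / tau_s)), 0)
  temps <- T0_K + drift_K_per_s * times + rise +
    stats::rnorm(length(times), 0, noise_sd_K)
  out <- list(times_s = times, temps_K = temps,
              ignition_time_s = ignition_time_s, kind = kind,
              delta_T_true_K = dT)
  if (kind == "sample") {
    out$sample_mass_g <- sample_mass_g
    out$fuel_mass_g <- fuel_mass_g
  } else {
    out$benzoic_mass_g <- benzoic_mass_g
    out$benzoic_gcv_J_per_g <- benzoic_gcv_J_per_g
  }
  out
}

#' Simulate replicate raw readings for the scalar assays
#'
#' Back-computes the raw instrument readings implied by the declared truths
#' (e.g. titration volume = `tta (1 - h) / 0.450`, absorbance = `ppm / 396`,
#' dry weight = `fwt (1 - h)`) and adds Gaussian noise on the raw scale,
#' truncated at physical bounds.
#'
#' @param truth A [sample_truth()] row.
#' @param n Named integer vector of replicate counts per assay; defaults
#'   mirror the study protocol where it states them (4 sieving and
#'   calorimetry runs, 5 moisture weighings) and use 3-4 replicates
#'   elsewhere.
#' @param noise An [assay_noise()] list.
#' @param seed Optional integer seed.
#' @return A named list of tibbles: `density`, `swelling`, `moisture`,
#'   `cyanide`, `acidity`, each one row per replicate with the raw readings
#'   of that assay's input schema.
#' @export
simulate_scalar_assays <- function(truth,
                                   n = c(density = 3, swelling = 3,
                                         moisture = 5, cyanide = 4,
                                         acidity = 3),
                                   noise = assay_noise(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("density", "swelling", "moisture", "cyanide", "acidity")
  if (!all(need %in% names(n))) {
    stop("`n` must name replicate counts for: ", paste(need, collapse = ", "))
  }
  id <- truth$sample_id
  h <- truth$moisture_fraction

  v_bulk <- 10 / truth$bulk_density_g_cm3
  density <- tibble::tibble(
    sample_id = id, trial_id = seq_len(n[["density"]]),
    sample_mass_g = 10.00,
    tapped_volume_cm3 = pmax(
      v_bulk + stats::rnorm(n[["density"]], 0, noise$volume_sd_cm3), 0.1)
  )
  v0 <- 10 / truth$bulk_density_g_cm3
  swelling <- tibble::tibble(
    sample_id = id, trial_id = seq_len(n[["swelling"]]),
    initial_volume_ml = pmax(
      v0 + stats::rnorm(n[["swelling"]], 0, noise$swell_volume_sd_ml), 0.1),
    swollen_volume_ml = pmax(
      v0 * truth$swelling_index +
        stats::rnorm(n[["swelling"]], 0, noise$swell_volume_sd_ml), 0.1)
  )
  fwt <- 10.00 + stats::rnorm(n[["moisture"]], 0, noise$fresh_sd_g)
  dwt <- pmin(pmax(fwt * (1 - h) +
                     stats::rnorm(n[["moisture"]], 0, noise$dry_sd_g), 0.1),
              fwt)
  moisture <- tibble::tibble(
    sample_id = id, trial_id = seq_len(n[["moisture"]]),
    fresh_weight_g = fwt, dry_weight_g = dwt
  )
  cyanide <- tibble::tibble(
    sample_id = id, trial_id = seq_len(n[["cyanide"]]),
    absorbance_510nm = pmax(
      truth$cyanide_ppm / 396 +
        stats::rnorm(n[["cyanide"]], 0, noise$absorbance_sd), 0),
    sample_mass_mg = 100, elution_volume_ml = 5.0
  )
  acidity <- tibble::tibble(
    sample_id = id, trial_id = seq_len(n[["acidity"]]),
    titration_volume_ml = pmax(
      truth$tta_percent * (1 - h) / 0.450 +
        stats::rnorm(n[["acidity"]], 0, noise$titration_sd_ml), 0)
  )
  list(density = density, swelling = swelling, moisture = moisture,
       cyanide = cyanide, acidity = acidity)
}

#' Simulate a balanced 2 x 2 factorial experiment
#'
#' Responses are grand mean + declared sum-to-zero main effects + declared
#' interaction + Gaussian noise. Scalar effects are applied as -e at the
#' first (alphabetical) level and +e at the second; the scalar interaction
#' is +g in the concordant cells and -g in the discordant ones.
#'
#' @param grand_mean Overall mean response.
#' @param effect_a,effect_b Scalar half-differences of the two main effects.
#' @param interaction Scalar interaction term.
#' @param r Replicates per cell (>= 2).
#' @param sd Response noise SD.
#' @param levels_a,levels_b Level labels.
#' @param seed Optional integer seed.
#' @param ... Passed to [factorial_dataset()] (factor names, display scale).
#' @return A [factorial_dataset()].
#' @export
simulate_factorial <- function(grand_mean = 1, effect_a = 0, effect_b = 0,
                               interaction = 0, r = 4, sd = 0.05,
                               levels_a = c("fine", "coarse"),
                               levels_b = c("dry", "humid"),
                               seed = NULL, ...) {
  if (r < 2) stop("At least two replicates per cell are required.")
  if (!is.null(seed)) set.seed(seed)
  la <- sort(levels_a)
  lb <- sort(levels_b)
  grid <- tidyr::expand_grid(a = la, b = lb, replicate = seq_len(r))
  ea <- ifelse(grid$a == la[1], -effect_a, effect_a)
  eb <- ifelse(grid$b == lb[1], -effect_b, effect_b)
  gab <- ifelse((grid$a == la[1]) == (grid$b == lb[1]),
                interaction, -interaction)
  y <- grand_mean + ea + eb + gab + stats::rnorm(nrow(grid), 0, sd)
  factorial_dataset(grid$a, grid$b, y, ...)
}

#' Demonstration truth set: 14 market samples
#'
#' A fixed set of 14 `sample_truth` records named after gari collection
#' sites in Maritime Togo (processing centres and markets), with truths
#' spread across the ranges typical of Togolese market gari. It is a
#' demonstration preset for exercising the pipeline end-to-end; it does not
#' reproduce any measured dataset.
#'
#' @return A 14-row `sample_truth` tibble.
#' @export
togo_maritime_truths <- function() {
  ids <- c("Agoe I", "Agoe II", "Agoe III", "Agoe IV",
           "Davie I", "Davie II", "Gape-Batekpo", "Gape-Nyassive",
           "Tabligbo I", "Tabligbo II", "Tabligbo III",
           "Vogan I", "Vogan II", "Vogan VI")
  sample_truth(
    sample_id = ids,
    median_um = c(700, 690, 830, 705, 745, 640, 660, 620,
                  715, 725, 655, 585, 840, 580),
    sigma_ln = c(0.45, 0.42, 0.40, 0.48, 0.44, 0.46, 0.41, 0.45,
                 0.43, 0.40, 0.47, 0.42, 0.44, 0.41),
    bulk_density_g_cm3 = c(0.615, 0.625, 0.605, 0.665, 0.680, 0.675,
                           0.625, 0.635, 0.635, 0.645, 0.665, 0.645,
                           0.565, 0.605),
    swelling_index = c(3.55, 3.60, 3.58, 4.20, 4.10, 4.05, 3.50, 3.55,
                       3.65, 3.42, 3.38, 3.80, 3.45, 3.36),
    moisture_fraction = c(0.0655, 0.0632, 0.0675, 0.0710, 0.0615, 0.0690,
                          0.0460, 0.0465, 0.0828, 0.0815, 0.0880, 0.0718,
                          0.0762, 0.0885),
    gcv_kJ_g = c(15.62, 15.58, 15.62, 15.66, 15.56, 15.56, 15.70, 15.71,
                 15.56, 15.60, 15.64, 15.68, 15.70, 15.56),
    cyanide_ppm = c(1.6, 1.8, 0.6, 0.9, 0.8, 2.4, 0.5, 3.2,
                    1.9, 0.6, 2.7, 2.0, 2.0, 0.5),
    tta_percent = c(1.27, 0.82, 1.11, 0.73, 0.62, 1.33, 0.60, 0.66,
                    1.04, 0.99, 1.50, 0.97, 1.10, 1.05)
  )
}

#' Simulate the full raw dataset of a quality-control study
#'
#' Generates every raw reading the pipeline consumes for each sample in a
#' truth table: sieve trials, scalar-assay replicates, and bomb-calorimeter
#' firings plus shared benzoic-acid calibration runs.
#'
#' @param truths A `sample_truth` tibble (e.g. [togo_maritime_truths()]).
#' @param spec A [sieve_spec()].
#' @param cfg A [calorimeter_config()].
#' @param K_J_per_K True calorimeter constant, J/K.
#' @param n_sieve,n_calorimetry Replicate firings/sievings per sample.
#' @param n_calibration Number of benzoic-acid calibration firings.
#' @param n Replicate counts for the scalar assays (see
#'   [simulate_scalar_assays()]).
#' @param noise An [assay_noise()] list.
#' @param seed Integer seed (mandatory for a reproducible study).
#' @return A list of raw data: `sieve_trials` (long tibble), the five
#'   scalar-assay tibbles, `calibration_runs` and `sample_runs` (lists of
#'   trace objects), plus the `spec`, `cfg` and truths used.
#' @export
simulate_study <- function(truths = togo_maritime_truths(),
                           spec = sieve_spec(),
                           cfg = calorimeter_config(),
                           K_J_per_K = 450,
                           n_sieve = 4, n_calorimetry = 4,
                           n_calibration = 2,
                           n = c(density = 3, swelling = 3, moisture = 5,
                                 cyanide = 4, acidity = 3),
                           noise = assay_noise(), seed = 1) {
  set.seed(seed)
  sieve_rows <- list()
  scalar <- list()
  sample_runs <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    for (j in seq_len(n_sieve)) {
      m <- simulate_sieve_trial(tr, spec, noise_sd_g = noise$sieve_mass_sd_g)
      sieve_rows[[length(sieve_rows) + 1]] <- tibble::tibble(
        sample_id = tr$sample_id, trial_id = j,
        sieving_time_min = if (j %% 2 == 1) 10 else 15,
        class_lower_um = spec$classes$lower_um,
        class_upper_um = spec$classes$upper_um,
        retained_mass_g = m
      )
    }
    scalar[[i]] <- simulate_scalar_assays(tr, n = n, noise = noise)
    for (j in seq_len(n_calorimetry)) {
      run <- simulate_calorimeter_run(
        "sample", cfg, K_J_per_K,
        gcv_sample_J_per_g = tr$gcv_kJ_g * 1000,
        sample_mass_g = max(stats::rnorm(1, 0.320, 0.010), 0.05),
        fuel_mass_g = max(stats::rnorm(1, 0.080, 0.005), 0.01),
        noise_sd_K = noise$trace_sd_K
      )
      run$sample_id <- tr$sample_id
      run$trial_id <- j
      sample_runs[[length(sample_runs) + 1]] <- run
    }
  }
  calibration_runs <- lapply(seq_len(n_calibration), function(j) {
    simulate_calorimeter_run("calibration", cfg, K_J_per_K,
                             noise_sd_K = noise$trace_sd_K)
  })
  bind_assay <- function(field) {
    dplyr::bind_rows(lapply(scalar, `[[`, field))
  }
  list(
    truths = truths, spec = spec, cfg = cfg,
    sieve_trials = dplyr::bind_rows(sieve_rows),
    density = bind_assay("density"),
    swelling = bind_assay("swelling"),
    moisture = bind_assay("moisture"),
    cyanide = bind_assay("cyanide"),
    acidity = bind_assay("acidity"),
    calibration_runs = calibration_runs,
    sample_runs = sample_runs
  )
}
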