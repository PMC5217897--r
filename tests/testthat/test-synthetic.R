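truth1 <- sample_truth("S1", median_um = 650, sigma_ln = 0.45,
                       bulk_density_g_cm3 = 0.63, swelling_index = 3.6,
                       moisture_fraction = 0.08, gcv_kJ_g = 15.6,
                       cyanide_ppm = 2.0, tta_percent = 1.0)

test_that("truth records are bounds-checked", {
  expect_error(sample_truth("x", 650, -0.1, 0.6, 3.5, 0.08, 15.6, 2, 1),
               "sigma_ln")
  expect_error(sample_truth("x", 650, 0.4, 0.6, 3.5, 0.5, 15.6, 2, 1),
               "moisture")
  expect_error(sample_truth("x", 650, 0.4, 2.0, 3.5, 0.08, 15.6, 2, 1),
               "bulk_density")
})

test_that("identical seed and truth give identical generated data", {
  a <- simulate_sieve_trial(truth1, seed = 11)
  b <- simulate_sieve_trial(truth1, seed = 11)
  expect_identical(a, b)
  ra <- simulate_scalar_assays(truth1, seed = 12)
  rb <- simulate_scalar_assays(truth1, seed = 12)
  expect_identical(ra, rb)
  ca <- simulate_calorimeter_run("sample", seed = 13)
  cb <- simulate_calorimeter_run("sample", seed = 13)
  expect_identical(ca, cb)
  sa <- simulate_study(togo_maritime_truths()[1:2, ], n_calorimetry = 1,
                       n_calibration = 1, seed = 14)
  sb <- simulate_study(togo_maritime_truths()[1:2, ], n_calorimetry = 1,
                       n_calibration = 1, seed = 14)
  expect_identical(sa, sb)
})

test_that("generated sieve trials satisfy the consuming type invariants", {
  spec <- sieve_spec()
  for (seed in 1:200) {
    m <- simulate_sieve_trial(truth1, spec, seed = seed)
    expect_true(all(m >= 0))
    expect_equal(sum(m), 100, tolerance = 1e-9)
    d <- mass_fractions(m, spec)
    expect_equal(sum(d$mass_fraction), 1, tolerance = 1e-9)
    expect_true(all(diff(d$cumulative) >= -1e-12))
  }
})

test_that("a near-degenerate lognormal puts all mass in one class", {
  spec <- sieve_spec()
  m <- simulate_sieve_trial(
    sample_truth("pt", 600, 1e-6, 0.6, 3.5, 0.08, 15.6, 2, 1),
    spec, noise_sd_g = 0, seed = 1)
  expect_equal(m[spec$classes$lower_um == 500], 100, tolerance = 1e-6)
  expect_error(simulate_sieve_trial(
    within(truth1, sigma_ln <- 0), spec), "positive")
})

test_that("noise-free sieve trials reproduce the discretised truth exactly", {
  spec <- sieve_spec()
  m <- simulate_sieve_trial(truth1, spec, noise_sd_g = 0, seed = 2)
  p <- plnorm(spec$classes$upper_um, log(650), 0.45) -
    plnorm(spec$classes$lower_um, log(650), 0.45)
  d_truth <- mass_fractions(p / sum(p) * 100, spec)
  d_sim <- mass_fractions(m, spec)
  expect_equal(weighted_mean_diameter(d_sim),
               weighted_mean_diameter(d_truth), tolerance = 1e-9)
})

test_that("the recovered median is unbiased to within 2% at default noise", {
  spec <- sieve_spec()
  set.seed(3)
  med <- replicate(500, {
    m <- simulate_sieve_trial(truth1, spec)
    median_diameter(mass_fractions(m, spec))
  })
  expect_lt(abs(mean(med) - truth1$median_um) / truth1$median_um, 0.02)
})

test_that("zero-noise scalar assays recover every truth exactly", {
  zero <- assay_noise(0, 0, 0, 0, 0, 0, 0, 0)
  r <- simulate_scalar_assays(truth1, noise = zero, seed = 4)
  expect_equal(bulk_density(r$density$sample_mass_g,
                            r$density$tapped_volume_cm3),
               rep(0.63, 3), tolerance = 1e-9)
  expect_equal(swelling_index(r$swelling$initial_volume_ml,
                              r$swelling$swollen_volume_ml),
               rep(3.6, 3), tolerance = 1e-9)
  expect_equal(moisture_content(r$moisture$fresh_weight_g,
                                r$moisture$dry_weight_g),
               rep(0.08, 5), tolerance = 1e-9)
  expect_equal(cyanide_ppm(r$cyanide$absorbance_510nm),
               rep(2.0, 4), tolerance = 1e-9)
  expect_equal(corrected_tta(r$acidity$titration_volume_ml, 0.08),
               rep(1.0, 3), tolerance = 1e-9)
})

test_that("zero-cyanide truth floors the absorbance at the blank", {
  t0 <- sample_truth("blank", 650, 0.45, 0.63, 3.6, 0.08, 15.6,
                     cyanide_ppm = 0, tta_percent = 1)
  r <- simulate_scalar_assays(t0, noise = assay_noise(absorbance_sd = 0),
                              seed = 5)
  expect_true(all(r$cyanide$absorbance_510nm == 0))
  expect_true(all(cyanide_ppm(r$cyanide$absorbance_510nm) == 0))
})

test_that("moisture replicates recover the truth within 0.01 absolute", {
  set.seed(6)
  est <- replicate(100, {
    r <- simulate_scalar_assays(
      truth1, n = c(density = 3, swelling = 3, moisture = 5,
                    cyanide = 4, acidity = 3),
      noise = assay_noise(dry_sd_g = 0.02))
    mean(moisture_content(r$moisture$fresh_weight_g, r$moisture$dry_weight_g))
  })
  expect_true(all(abs(est - 0.08) < 0.01))
})

test_that("calorimeter runs at sigma = 0.02 K recover GCV within 0.15 kJ/g", {
  cfg <- calorimeter_config()
  set.seed(7)
  ok <- replicate(50, {
    run <- simulate_calorimeter_run("sample", cfg, 450, 15600, 0.32, 0.08,
                                    noise_sd_K = 0.02)
    res <- reduce_sample_run(run$times_s, run$temps_K, run$ignition_time_s,
                             0.32, 0.08, 450, cfg)
    abs(res$gcv_sample_kJ_per_g - 15.6) <= 0.15
  })
  expect_gte(mean(ok), 0.95)
})

test_that("calibration firings recover the configured calorimeter constant", {
  cfg <- calorimeter_config()
  cal <- simulate_calorimeter_run("calibration", cfg, K_J_per_K = 450,
                                  noise_sd_K = 0, drift_K_per_s = 0)
  dt <- extract_delta_T(cal$times_s, cal$temps_K, cal$ignition_time_s)
  K <- calorimeter_constant(dt$delta_T_K, cal$benzoic_mass_g,
                            cal$benzoic_gcv_J_per_g, cfg)
  expect_lt(abs(K - 450), 2) # limited only by the trace discretisation
  set.seed(8)
  cal2 <- simulate_calorimeter_run("calibration", cfg, 450, noise_sd_K = 0.02)
  dt2 <- extract_delta_T(cal2$times_s, cal2$temps_K, cal2$ignition_time_s)
  K2 <- calorimeter_constant(dt2$delta_T_K, cal2$benzoic_mass_g,
                             cal2$benzoic_gcv_J_per_g, cfg)
  expect_lt(abs(K2 - 450), 25)
})

test_that("factorial simulation reproduces declared effects", {
  d <- simulate_factorial(1, 0.2, 0.4, 0.1, r = 4, sd = 0, seed = 9)
  dec <- decompose_factorial(d)
  expect_equal(sort(unname(dec$effect_a)), c(-0.2, 0.2), tolerance = 1e-12)
  expect_equal(sort(unname(dec$effect_b)), c(-0.4, 0.4), tolerance = 1e-12)
  expect_equal(sort(unique(round(as.vector(dec$interaction), 12))),
               c(-0.1, 0.1))
  # zero declared interaction stays insignificant in most noisy replays
  set.seed(10)
  p_int <- replicate(200, {
    d <- simulate_factorial(1, 0.3, 0.3, 0, r = 4, sd = 0.05)
    factorial_anova(decompose_factorial(d))$p.value[3]
  })
  expect_gte(mean(p_int > 0.05), 0.90)
})
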