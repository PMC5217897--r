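cfg0 <- calorimeter_config()

make_step_trace <- function(T0 = 298, dT = 2, drift = 0, t_ign = 600,
                            t_end = 1800, dt = 2) {
  t <- seq(0, t_end, by = dt)
  list(t = t, y = T0 + drift * t + ifelse(t > t_ign, dT, 0), ign = t_ign)
}

test_that("temperature rise of an ideal step trace is the step height", {
  tr <- make_step_trace(dT = 2.000)
  got <- extract_delta_T(tr$t, tr$y, tr$ign)
  expect_equal(got$delta_T_K, 2.000, tolerance = 1e-8)
})

test_that("identical linear drift before and after cancels exactly", {
  for (b in c(-2e-4, 5e-5, 1e-3)) {
    tr <- make_step_trace(dT = 1.500, drift = b)
    got <- extract_delta_T(tr$t, tr$y, tr$ign)
    expect_equal(got$delta_T_K, 1.500, tolerance = 1e-8)
  }
})

test_that("extraction is invariant under time and temperature offsets", {
  run <- simulate_calorimeter_run("sample", seed = 21)
  a <- extract_delta_T(run$times_s, run$temps_K, run$ignition_time_s)
  b <- extract_delta_T(run$times_s + 137, run$temps_K + 25.4,
                       run$ignition_time_s + 137)
  expect_equal(a$delta_T_K, b$delta_T_K, tolerance = 1e-9)
})

test_that("noisy synthetic traces recover the true rise within 0.05 K", {
  set.seed(31)
  for (i in 1:20) {
    run <- simulate_calorimeter_run("sample", gcv_sample_J_per_g = 15000,
                                    sample_mass_g = 0.32, fuel_mass_g = 0.08,
                                    drift_K_per_s = 2e-5, noise_sd_K = 0.02)
    got <- extract_delta_T(run$times_s, run$temps_K, run$ignition_time_s)
    expect_lt(abs(got$delta_T_K - run$delta_T_true_K), 0.05)
  }
})

test_that("degenerate traces raise the documented errors", {
  # flat trace: no combustion
  t <- seq(0, 1800, by = 2)
  expect_error(extract_delta_T(t, rep(300, length(t)), 600),
               "Failed combustion")
  # too few points around ignition
  expect_error(extract_delta_T(c(0, 10, 600, 610), c(1, 1, 2, 2), 300),
               "Insufficient")
  expect_error(extract_delta_T(c(0, 10, 20), c(1, 1, 1), 5), "Insufficient")
})

test_that("calorimeter constant follows the calibration balance", {
  # perfect water-only calorimeter: numerator equals water term exactly
  cfg <- calorimeter_config(water_mass_g = 1000,
                            water_heat_capacity_J_per_gK = 4.184,
                            wire_gcv_J_per_g = 5000, wire_mass_g = 0.01)
  dT <- 6
  mB <- (cfg$water_mass_g * cfg$water_heat_capacity_J_per_gK * dT -
           cfg$wire_gcv_J_per_g * cfg$wire_mass_g) / 26460
  expect_equal(calorimeter_constant(dT, mB, 26460, cfg), 0,
               tolerance = 1e-9)
  # term-by-term hand evaluation
  cfg2 <- calorimeter_config(wire_gcv_J_per_g = 5000, wire_mass_g = 0.01)
  hand <- (26460 * 1.000 + 5000 * 0.01) / 6.000 - 1000 * 4.184
  expect_equal(calorimeter_constant(6.000, 1.000, 26460, cfg2), hand)
  # homogeneity: doubling numerator terms and the rise leaves K unchanged
  cfg3 <- calorimeter_config(wire_gcv_J_per_g = 5000, wire_mass_g = 0.02)
  expect_equal(calorimeter_constant(12.000, 2.000, 26460, cfg3), hand)
  expect_error(calorimeter_constant(0, 1, 26460, cfg2), "positive")
  expect_warning(calorimeter_constant(10, 1.0, 26460, cfg2), "Negative")
})

test_that("mixture and sample calorific values follow the energy balance", {
  # K = 0, no wire term beyond epsilon, direct ratio
  cfg <- calorimeter_config(water_mass_g = 1000,
                            water_heat_capacity_J_per_gK = 4.184,
                            wire_gcv_J_per_g = 1e-12, wire_mass_g = 1e-12)
  dT <- 10000 / (1000 * 4.184)
  expect_equal(gcv_mixture(dT, 0.5, 0, cfg), 20000, tolerance = 1e-6)
  # unspiked sample: H_h,G = H_h,M
  expect_equal(gcv_sample(18000, 0.3, 0, cfg0), 18000)
  # equal masses, mixture value exactly midway: sample is the mirror of fuel
  HhF <- cfg0$fuel_gcv_J_per_g
  HhG <- 15600
  HhM <- (HhG + HhF) / 2
  expect_equal(gcv_sample(HhM, 0.2, 0.2, cfg0), HhG, tolerance = 1e-9)
  expect_error(gcv_sample(15000, 0, 0.1, cfg0), "positive")
})

test_that("the algebraic chain round-trips exactly and is monotone in fuel", {
  set.seed(17)
  for (i in 1:20) {
    cfg <- calorimeter_config(
      water_mass_g = runif(1, 500, 2000),
      water_heat_capacity_J_per_gK = 4.184,
      wire_gcv_J_per_g = runif(1, 4000, 9000),
      wire_mass_g = runif(1, 0.005, 0.02),
      fuel_gcv_J_per_g = runif(1, 40000, 48000))
    K <- runif(1, 100, 900)
    HhG <- runif(1, 12000, 20000)
    mG <- runif(1, 0.2, 0.5)
    mF <- runif(1, 0.05, 0.12)
    run <- simulate_calorimeter_run("sample", cfg, K, HhG, mG, mF,
                                    noise_sd_K = 0, drift_K_per_s = 0)
    HhM <- gcv_mixture(run$delta_T_true_K, mG + mF, K, cfg)
    expect_equal(gcv_sample(HhM, mG, mF, cfg) / HhG, 1, tolerance = 1e-9)
    # calibration leg: implied rise reproduces the configured constant
    cal <- simulate_calorimeter_run("calibration", cfg, K,
                                    benzoic_mass_g = 1, noise_sd_K = 0,
                                    drift_K_per_s = 0)
    expect_equal(calorimeter_constant(cal$delta_T_true_K, 1, 26460, cfg) / K,
                 1, tolerance = 1e-9)
    # strictly decreasing in fuel mass when the fuel is richer than the mix
    expect_lt(gcv_sample(HhM, mG, mF + 0.01, cfg),
              gcv_sample(HhM, mG, mF, cfg))
  }
})

test_that("zero-noise trace reduction recovers the truth closely", {
  run <- simulate_calorimeter_run("sample", cfg0, 450, 15600, 0.32, 0.08,
                                  noise_sd_K = 0, drift_K_per_s = 1e-5)
  got <- extract_delta_T(run$times_s, run$temps_K, run$ignition_time_s)
  expect_lt(abs(got$delta_T_K - run$delta_T_true_K), 1e-3)
  res <- reduce_sample_run(run$times_s, run$temps_K, run$ignition_time_s,
                           0.32, 0.08, 450, cfg0)
  expect_lt(abs(res$gcv_sample_kJ_per_g - 15.6), 0.02)
})
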