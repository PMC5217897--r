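#' Calorimeter configuration
#'
#' Fixed quantities of a static-jacket bomb calorimeter needed to reduce a
#' run: the water charge and its heat capacity, the ignition wire's mass and
#' gross calorific value, and the gross calorific value of the spiking fuel
#' (light fuel oil added to low-energy samples to ensure complete
#' combustion). The certified values are configuration, not constants: they
#' depend on the wire and fuel batch in use.
#'
#' @param water_mass_g Mass of distilled water in the bath, g.
#' @param water_heat_capacity_J_per_gK Specific heat capacity of water,
#'   J/(g K).
#' @param wire_gcv_J_per_g Gross calorific value of the ignition wire, J/g.
#' @param wire_mass_g Mass of ignition wire burned per firing, g.
#' @param fuel_gcv_J_per_g Gross calorific value of the spiking fuel, J/g.
#' @return A `calorimeter_config` list.
#' @export
calorimeter_config <- function(water_mass_g = 1000,
                               water_heat_capacity_J_per_gK = 4.184,
                               wire_gcv_J_per_g = 6700,
                               wire_mass_g = 0.010,
                               fuel_gcv_J_per_g = 45400) {
  vals <- c(water_mass_g, water_heat_capacity_J_per_gK,
            wire_gcv_J_per_g, wire_mass_g, fuel_gcv_J_per_g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("All calorimeter configuration values must be positive.")
  }
  structure(
    list(
      water_mass_g = water_mass_g,
      water_heat_capacity_J_per_gK = water_heat_capacity_J_per_gK,
      wire_gcv_J_per_g = wire_gcv_J_per_g,
      wire_mass_g = wire_mass_g,
      fuel_gcv_J_per_g = fuel_gcv_J_per_g
    ),
    class = "calorimeter_config"
  )
}

running_mean <- function(x, k) {
  # centred running mean, shrinking the window at the edges
  n <- length(x)
  h <- k %/% 2
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Corrected temperature rise of a bomb-calorimeter trace
#'
#' Extracts the temperature rise from a time-stamped trace with a quiet fore
#' period, an ignition-driven rise, and an after period that may drift. Both
#' drift periods are fitted linearly and extrapolated to the mid-rise time
#' (where the trace crosses halfway between the two fitted lines); the rise
#' is the gap between the two lines there, which cancels equal linear drift
#' exactly.
#'
#' Fit windows are auto-detected: the fore window is everything up to the
#' ignition time; the rise region is the contiguous run of points, around
#' the peak slope, whose slope exceeds the fore-period drift slope by more
#' than a threshold (default: `5 * MAD` of the fore-period slope excess,
#' floored at 5% of the peak excess); the after window starts two rise
#' durations past the rise end, so that the exponential tail of the
#' approach to equilibrium has died out. Explicit windows override the
#' detection.
#'
#' @param times_s Ascending timestamps, s.
#' @param temps_K Temperatures, K (any fixed offset cancels).
#' @param ignition_time_s Firing time, s.
#' @param fore_window,after_window Optional `c(start, end)` times (s)
#'   overriding the automatic fit windows.
#' @param slope_threshold Optional slope-excess threshold in K/s overriding
#'   the automatic one.
#' @param smooth_k Width (points) of the running mean used for slope
#'   detection and the mid-rise crossing; odd, default 9.
#' @return A list with `delta_T_K` (the corrected rise), `t_mid_s`, the two
#'   window time ranges, and the fitted drift coefficients.
#' @export
extract_delta_T <- function(times_s, temps_K, ignition_time_s,
                            fore_window = NULL, after_window = NULL,
                            slope_threshold = NULL, smooth_k = 9) {
  t <- as.numeric(times_s)
  y <- as.numeric(temps_K)
  if (length(t) != length(y) || anyNA(t) || anyNA(y)) {
    stop("Trace times and temperatures must be equal-length and complete.")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("Trace times must be strictly increasing.")
  }
  if (sum(t < ignition_time_s) < 3 || sum(t > ignition_time_s) < 3) {
    stop("Insufficient trace: need at least 3 points on each side of ignition.")
  }

  fore_idx <- if (is.null(fore_window)) {
    which(t <= ignition_time_s)
  } else {
    which(t >= fore_window[1] & t <= fore_window[2])
  }
  if (length(fore_idx) < 2) {
    stop("Insufficient trace: fore-period window has fewer than 2 points.")
  }
  fore_fit <- stats::lm.fit(cbind(1, t[fore_idx]), y[fore_idx])$coefficients

  if (is.null(after_window)) {
    sm <- running_mean(y, smooth_k)
    h <- max(smooth_k %/% 2, 1L)
    n <- length(t)
    ctr <- seq.int(1L + h, n - h)
    slope <- (sm[ctr + h] - sm[ctr - h]) / (t[ctr + h] - t[ctr - h])
    excess <- slope - fore_fit[2]
    post <- which(t[ctr] > ignition_time_s)
    if (length(post) < 3) stop("Insufficient trace after ignition.")
    fore_sl <- excess[t[ctr] <= ignition_time_s]
    peak <- post[which.max(excess[post])]
    thr <- max(5 * stats::mad(fore_sl, na.rm = TRUE),
               0.05 * excess[peak])
    if (!is.null(slope_threshold)) thr <- slope_threshold
    if (excess[peak] <= thr) {
      stop("Failed combustion: no temperature rise detected after ignition.")
    }
    rise_end <- peak
    while (rise_end < length(ctr) && excess[rise_end + 1] > thr) {
      rise_end <- rise_end + 1
    }
    t_rise_end <- t[ctr[rise_end]]
    after_start <- t_rise_end + 2 * (t_rise_end - ignition_time_s)
    after_idx <- which(t >= after_start)
  } else {
    after_idx <- which(t >= after_window[1] & t <= after_window[2])
  }
  if (length(after_idx) < 2) {
    stop("Insufficient trace: after-period window has fewer than 2 points.")
  }
  after_fit <- stats::lm.fit(cbind(1, t[after_idx]), y[after_idx])$coefficients

  # mid-rise time: first crossing of the smoothed trace with the midline
  sm_all <- running_mean(y, smooth_k)
  midline <- (fore_fit[1] + after_fit[1]) / 2 +
    (fore_fit[2] + after_fit[2]) / 2 * t
  g <- sm_all - midline
  cand <- which(t >= ignition_time_s & t < t[max(after_idx)])
  cross <- cand[g[cand] >= 0][1]
  if (is.na(cross) || cross <= 1) {
    t_mid <- ignition_time_s
  } else {
    g0 <- g[cross - 1]
    g1 <- g[cross]
    t_mid <- if (g1 == g0) t[cross] else
      t[cross - 1] + (0 - g0) / (g1 - g0) * (t[cross] - t[cross - 1])
  }

  dT <- unname((after_fit[1] + after_fit[2] * t_mid) -
               (fore_fit[1] + fore_fit[2] * t_mid))
  if (dT <= 0) {
    stop("Failed combustion: extracted temperature rise is not positive.")
  }
  list(
    delta_T_K = dT,
    t_mid_s = t_mid,
    fore_window_s = range(t[fore_idx]),
    after_window_s = range(t[after_idx]),
    fore_drift_K_per_s = unname(fore_fit[2]),
    after_drift_K_per_s = unname(after_fit[2])
  )
}

#' Calorimeter constant from a benzoic-acid calibration firing
#'
#' The effective heat capacity of the apparatus beyond its water charge:
#' \eqn{K = (H_{h,B} m_B + H_{h,I} m_I)/\Delta T - m_W c_W}.
#'
#' @param delta_T_K Corrected temperature rise of the calibration firing, K.
#' @param benzoic_mass_g Mass of the benzoic acid pellet, g.
#' @param benzoic_gcv_J_per_g Certified gross calorific value of benzoic
#'   acid, J/g (26460 J/g for standard-grade pellets).
#' @param cfg A [calorimeter_config()].
#' @return Calorimeter constant in J/K. A negative value (heat release
#'   smaller than the water charge alone can absorb) is flagged with a
#'   warning.
#' @export
calorimeter_constant <- function(delta_T_K, benzoic_mass_g,
                                 benzoic_gcv_J_per_g = 26460, cfg) {
  stopifnot(inherits(cfg, "calorimeter_config"))
  if (!is.finite(delta_T_K) || delta_T_K <= 0) {
    stop("Temperature rise must be positive.")
  }
  if (benzoic_mass_g <= 0) stop("Benzoic acid mass must be positive.")
  K <- (benzoic_gcv_J_per_g * benzoic_mass_g +
          cfg$wire_gcv_J_per_g * cfg$wire_mass_g) / delta_T_K -
    cfg$water_mass_g * cfg$water_heat_capacity_J_per_gK
  if (K < 0) {
    warning("Negative calorimeter constant: check calibration inputs.")
  }
  K
}

#' Gross calorific value of the sample-fuel mixture
#'
#' \eqn{H_{h,M} = ((m_W c_W + K)\,\Delta T - H_{h,I} m_I)/m_M} for a firing
#' of a mixture of total mass `mixture_mass_g`.
#'
#' @param delta_T_K Corrected temperature rise, K.
#' @param mixture_mass_g Combined mass of sample and spiking fuel, g.
#' @param K_J_per_K Calorimeter constant, J/K.
#' @param cfg A [calorimeter_config()].
#' @return Gross calorific value of the mixture, J/g.
#' @export
gcv_mixture <- function(delta_T_K, mixture_mass_g, K_J_per_K, cfg) {
  stopifnot(inherits(cfg, "calorimeter_config"))
  if (!is.finite(delta_T_K) || delta_T_K <= 0) {
    stop("Temperature rise must be positive.")
  }
  if (mixture_mass_g <= 0) stop("Mixture mass must be positive.")
  H <- ((cfg$water_mass_g * cfg$water_heat_capacity_J_per_gK + K_J_per_K) *
          delta_T_K - cfg$wire_gcv_J_per_g * cfg$wire_mass_g) / mixture_mass_g
  if (H < 0) {
    warning("Negative mixture calorific value: physically implausible run.")
  }
  H
}

#' Gross calorific value of the sample net of spiking fuel
#'
#' Removes the spiking-fuel contribution from the mixture value:
#' \eqn{H_{h,G} = (H_{h,M} m_M - H_{h,F} m_F)/m_G} with
#' \eqn{m_M = m_G + m_F}.
#'
#' @param gcv_mixture_J_per_g Gross calorific value of the mixture, J/g.
#' @param sample_mass_g Sample mass, g.
#' @param fuel_mass_g Spiking fuel mass, g (0 for an unspiked firing).
#' @param cfg A [calorimeter_config()].
#' @return Gross calorific value of the sample, J/g.
#' @export
gcv_sample <- function(gcv_mixture_J_per_g, sample_mass_g, fuel_mass_g, cfg) {
  stopifnot(inherits(cfg, "calorimeter_config"))
  if (sample_mass_g <= 0) stop("Sample mass must be positive.")
  if (fuel_mass_g < 0) stop("Fuel mass cannot be negative.")
  m_M <- sample_mass_g + fuel_mass_g
  (gcv_mixture_J_per_g * m_M - cfg$fuel_gcv_J_per_g * fuel_mass_g) /
    sample_mass_g
}

#' Reduce one sample firing to a gross calorific value
#'
#' Convenience chain: trace to corrected temperature rise, rise to mixture
#' calorific value, mixture to sample value net of spiking fuel.
#'
#' @param times_s,temps_K,ignition_time_s The temperature trace (see
#'   [extract_delta_T()]).
#' @param sample_mass_g,fuel_mass_g Masses of sample and spiking fuel, g.
#' @param K_J_per_K Calorimeter constant from calibration, J/K.
#' @param cfg A [calorimeter_config()].
#' @param ... Passed to [extract_delta_T()].
#' @return A list with `delta_T_K`, `gcv_mixture_J_per_g`,
#'   `gcv_sample_J_per_g` and `gcv_sample_kJ_per_g`.
#' @export
reduce_sample_run <- function(times_s, temps_K, ignition_time_s,
                              sample_mass_g, fuel_mass_g, K_J_per_K, cfg,
                              ...) {
  dt <- extract_delta_T(times_s, temps_K, ignition_time_s, ...)
  HhM <- gcv_mixture(dt$delta_T_K, sample_mass_g + fuel_mass_g, K_J_per_K, cfg)
  HhG <- gcv_sample(HhM, sample_mass_g, fuel_mass_g, cfg)
  list(
    delta_T_K = dt$delta_T_K,
    gcv_mixture_J_per_g = HhM,
    gcv_sample_J_per_g = HhG,
    gcv_sample_kJ_per_g = HhG / 1000
  )
}
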