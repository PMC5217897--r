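#' Per-trial granulometry reduction
#'
#' Reduces a long sieve-trial table (one row per retained class) to one row
#' per trial with the median and mass-weighted mean diameters.
#'
#' @param sieve_trials Tibble in the sieve input schema (see
#'   [read_trials()]): `sample_id`, `trial_id`, `sieving_time_min`,
#'   `class_lower_um`, `class_upper_um`, `retained_mass_g`.
#' @param spec A [sieve_spec()] the class bounds must match.
#' @return Tibble: `sample_id`, `trial_id`, `sieving_time_min`, `median_um`,
#'   `weighted_mean_um`.
#' @export
reduce_granulometry <- function(sieve_trials, spec = sieve_spec()) {
  sieve_trials |>
    dplyr::group_by(.data$sample_id, .data$trial_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$class_lower_um)
      if (!isTRUE(all.equal(df$class_lower_um, spec$classes$lower_um)) ||
          !isTRUE(all.equal(df$class_upper_um, spec$classes$upper_um))) {
        stop("Schema error: trial classes do not match the sieve spec (",
             key$sample_id, ", trial ", key$trial_id, ").")
      }
      d <- mass_fractions(df$retained_mass_g, spec)
      tibble::tibble(
        sieving_time_min = df$sieving_time_min[1],
        median_um = median_diameter(d),
        weighted_mean_um = weighted_mean_diameter(d)
      )
    }) |>
    dplyr::ungroup()
}

#' Calibrate the calorimeter from benzoic-acid firings
#'
#' Reduces each calibration trace to its corrected temperature rise and
#' averages the resulting calorimeter constants.
#'
#' @param calibration_runs List of calibration runs, each a list with
#'   `times_s`, `temps_K`, `ignition_time_s`, `benzoic_mass_g` and
#'   `benzoic_gcv_J_per_g` (as produced by [simulate_calorimeter_run()] or
#'   assembled from a run manifest plus [read_trace()]).
#' @param cfg A [calorimeter_config()].
#' @return A list with the mean `K_J_per_K` and the per-run tibble.
#' @export
calibrate_calorimeter <- function(calibration_runs, cfg) {
  per_run <- dplyr::bind_rows(lapply(seq_along(calibration_runs), function(i) {
    r <- calibration_runs[[i]]
    dt <- extract_delta_T(r$times_s, r$temps_K, r$ignition_time_s)
    tibble::tibble(
      run = i, delta_T_K = dt$delta_T_K,
      K_J_per_K = calorimeter_constant(dt$delta_T_K, r$benzoic_mass_g,
                                       r$benzoic_gcv_J_per_g, cfg)
    )
  }))
  list(K_J_per_K = mean(per_run$K_J_per_K), per_run = per_run)
}

#' Per-firing calorimetry reduction
#'
#' @param sample_runs List of sample firings, each with `sample_id`,
#'   `trial_id`, the trace, `sample_mass_g` and `fuel_mass_g`.
#' @param cfg A [calorimeter_config()].
#' @param K_J_per_K Calibrated calorimeter constant, J/K.
#' @return Tibble: `sample_id`, `trial_id`, `delta_T_K`, `gcv_kJ_g`.
#' @export
reduce_calorimetry <- function(sample_runs, cfg, K_J_per_K) {
  dplyr::bind_rows(lapply(sample_runs, function(r) {
    res <- reduce_sample_run(r$times_s, r$temps_K, r$ignition_time_s,
                             r$sample_mass_g, r$fuel_mass_g, K_J_per_K, cfg)
    tibble::tibble(
      sample_id = r$sample_id, trial_id = r$trial_id,
      delta_T_K = res$delta_T_K, gcv_kJ_g = res$gcv_sample_kJ_per_g
    )
  }))
}

#' Run the full quality-control reduction on a raw study dataset
#'
#' Applies every assay reduction to the raw readings of a study (simulated
#' by [simulate_study()] or read from CSVs in the same schemas), joins the
#' per-sample mean moisture into the acidity correction, and aggregates
#' replicates into the per-sample summary table (one row per sample, one
#' mean/SD/n triple per parameter).
#'
#' @param raw List of raw study data: `sieve_trials`, `density`, `swelling`,
#'   `moisture`, `cyanide`, `acidity`, `calibration_runs`, `sample_runs`,
#'   plus the `spec` and `cfg` in use (see [simulate_study()]). The
#'   calorimetry entries may be `NULL`, in which case the calorific value
#'   columns are omitted.
#' @param chart A [color_chart()] for the semi-quantitative cyanide class.
#' @param moisture_override Optional named vector of per-sample moisture
#'   fractions to use in the acidity correction instead of the per-sample
#'   mean of the moisture assay.
#' @return A list: `table` (one `QCResultRow` per sample: each parameter's
#'   mean with `<parameter>_sd` and `<parameter>_n`), `per_trial` (long
#'   per-trial values), and `calibration` (the calorimeter calibration, if
#'   run).
#' @export
qc_report <- function(raw, chart = color_chart(), moisture_override = NULL) {
  spec <- if (is.null(raw$spec)) sieve_spec() else raw$spec
  gran <- reduce_granulometry(raw$sieve_trials, spec)

  per_trial <- dplyr::bind_rows(
    gran |>
      tidyr::pivot_longer(c("median_um", "weighted_mean_um"),
                          names_to = "parameter", values_to = "value") |>
      dplyr::select("sample_id", "parameter", "value"),
    raw$density |>
      dplyr::mutate(parameter = "bulk_density_g_cm3",
                    value = bulk_density(.data$sample_mass_g,
                                         .data$tapped_volume_cm3)) |>
      dplyr::select("sample_id", "parameter", "value"),
    raw$swelling |>
      dplyr::mutate(parameter = "swelling_index",
                    value = swelling_index(.data$initial_volume_ml,
                                           .data$swollen_volume_ml)) |>
      dplyr::select("sample_id", "parameter", "value"),
    raw$moisture |>
      dplyr::mutate(parameter = "moisture_percent",
                    value = 100 * moisture_content(.data$fresh_weight_g,
                                                   .data$dry_weight_g)) |>
      dplyr::select("sample_id", "parameter", "value"),
    raw$cyanide |>
      dplyr::mutate(parameter = "cyanide_ppm",
                    value = cyanide_ppm(.data$absorbance_510nm,
                                        .data$sample_mass_mg,
                                        .data$elution_volume_ml)) |>
      dplyr::select("sample_id", "parameter", "value")
  )

  # acidity: the moisture correction uses the per-sample mean moisture
  h_mean <- per_trial |>
    dplyr::filter(.data$parameter == "moisture_percent") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(h = mean(.data$value) / 100, .groups = "drop")
  if (!is.null(moisture_override)) {
    h_mean$h <- unname(moisture_override[h_mean$sample_id])
  }
  acid <- raw$acidity |>
    dplyr::left_join(h_mean, by = "sample_id") |>
    dplyr::mutate(parameter = "acidity_g_per_100g",
                  value = corrected_tta(.data$titration_volume_ml, .data$h)) |>
    dplyr::select("sample_id", "parameter", "value")
  per_trial <- dplyr::bind_rows(per_trial, acid)

  calibration <- NULL
  if (!is.null(raw$sample_runs) && length(raw$sample_runs) > 0) {
    cfg <- if (is.null(raw$cfg)) calorimeter_config() else raw$cfg
    calibration <- calibrate_calorimeter(raw$calibration_runs, cfg)
    gcv <- reduce_calorimetry(raw$sample_runs, cfg, calibration$K_J_per_K) |>
      dplyr::mutate(parameter = "gcv_kJ_g", value = .data$gcv_kJ_g) |>
      dplyr::select("sample_id", "parameter", "value")
    per_trial <- dplyr::bind_rows(per_trial, gcv)
  }

  agg <- aggregate_results(per_trial)
  params <- c("weighted_mean_um", "median_um", "bulk_density_g_cm3",
              "swelling_index", "moisture_percent", "gcv_kJ_g",
              "cyanide_ppm", "acidity_g_per_100g")
  params <- intersect(params, unique(agg$parameter))
  wide <- agg |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = params)) |>
    tidyr::pivot_wider(names_from = "parameter",
                       values_from = c("mean", "sd", "n"),
                       names_glue = "{parameter}{c(mean='', sd='_sd', n='_n')[.value]}")
  ord <- c("sample_id",
           unlist(lapply(params, function(p) c(p, paste0(p, "_sd"),
                                               paste0(p, "_n")))))
  wide <- wide[, intersect(ord, names(wide))]
  # chart classification of the per-sample photometric mean
  if ("cyanide_ppm" %in% names(wide)) {
    wide$cyanide_chart_ppm <- chart_class(wide$cyanide_ppm, chart)
  }
  list(table = wide, per_trial = per_trial, calibration = calibration)
}
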