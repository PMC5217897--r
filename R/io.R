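#' @importFrom rlang .data
NULL

# Input schemas: required columns, which must be numeric, and which must be
# non-negative / strictly positive.
.gariqc_schemas <- list(
  sieve = list(
    required = c("sample_id", "trial_id", "sieving_time_min",
                 "class_lower_um", "class_upper_um", "retained_mass_g"),
    numeric = c("trial_id", "sieving_time_min", "class_lower_um",
                "class_upper_um", "retained_mass_g"),
    nonneg = c("class_lower_um", "retained_mass_g"),
    positive = c("class_upper_um")
  ),
  density = list(
    required = c("sample_id", "trial_id", "sample_mass_g",
                 "tapped_volume_cm3"),
    numeric = c("trial_id", "sample_mass_g", "tapped_volume_cm3"),
    nonneg = character(), positive = c("sample_mass_g", "tapped_volume_cm3")
  ),
  swelling = list(
    required = c("sample_id", "trial_id", "initial_volume_ml",
                 "swollen_volume_ml"),
    numeric = c("trial_id", "initial_volume_ml", "swollen_volume_ml"),
    nonneg = character(),
    positive = c("initial_volume_ml", "swollen_volume_ml")
  ),
  moisture = list(
    required = c("sample_id", "trial_id", "fresh_weight_g", "dry_weight_g"),
    numeric = c("trial_id", "fresh_weight_g", "dry_weight_g"),
    nonneg = character(), positive = c("fresh_weight_g", "dry_weight_g")
  ),
  cyanide = list(
    required = c("sample_id", "trial_id", "absorbance_510nm",
                 "sample_mass_mg", "elution_volume_ml"),
    numeric = c("trial_id", "absorbance_510nm", "sample_mass_mg",
                "elution_volume_ml"),
    nonneg = "absorbance_510nm",
    positive = c("sample_mass_mg", "elution_volume_ml")
  ),
  acidity = list(
    required = c("sample_id", "trial_id", "titration_volume_ml"),
    numeric = c("trial_id", "titration_volume_ml"),
    nonneg = "titration_volume_ml", positive = character()
  ),
  trace = list(
    required = c("time_s", "temp_K"),
    numeric = c("time_s", "temp_K"),
    nonneg = character(), positive = character()
  ),
  manifest = list(
    required = c("run_id", "kind", "sample_id", "ignition_time_s",
                 "sample_mass_g", "fuel_mass_g", "benzoic_mass_g",
                 "benzoic_gcv_J_per_g", "trace_file"),
    numeric = c("ignition_time_s", "sample_mass_g", "fuel_mass_g",
                "benzoic_mass_g", "benzoic_gcv_J_per_g"),
    nonneg = "fuel_mass_g",
    positive = character()
  )
)

#' Read and validate a raw-readings CSV
#'
#' Reads one of the pipeline's input schemas from a comma-delimited,
#' period-decimal CSV (lines starting with `#` are treated as comments) and
#' validates it: missing columns raise a schema error; non-numeric cells and
#' sign violations are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param schema_id One of `"sieve"`, `"density"`, `"swelling"`,
#'   `"moisture"`, `"cyanide"`, `"acidity"`, `"trace"`.
#' @return A validated tibble.
#' @export
read_trials <- function(path, schema_id) {
  if (!file.exists(path)) stop("File not found: ", path)
  schema_id <- match.arg(schema_id, names(.gariqc_schemas))
  sch <- .gariqc_schemas[[schema_id]]
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), comment = "#", progress = FALSE)
  missing <- setdiff(sch$required, names(raw))
  if (length(missing) > 0) {
    stop("Schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), ".")
  }
  # data line numbers: header is line 1 (comments were stripped by readr)
  line_no <- seq_len(nrow(raw)) + 1L
  out <- raw
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop("Parse error in ", path, ", column `", col, "`: non-numeric ",
           "value(s) at line(s) ", paste(line_no[bad], collapse = ", "), ".")
    }
    out[[col]] <- v
  }
  for (col in sch$nonneg) {
    bad <- which(out[[col]] < 0)
    if (length(bad) > 0) {
      stop("Validation error in ", path, ", column `", col, "`: negative ",
           "value(s) at line(s) ", paste(line_no[bad], collapse = ", "), ".")
    }
  }
  for (col in sch$positive) {
    bad <- which(out[[col]] <= 0)
    if (length(bad) > 0) {
      stop("Validation error in ", path, ", column `", col, "`: ",
           "non-positive value(s) at line(s) ",
           paste(line_no[bad], collapse = ", "), ".")
    }
  }
  out
}

#' Write a result or raw-readings table as CSV
#'
#' Comma-delimited, period-decimal, locale-independent output. Numeric
#' columns are written at full double precision (up to 15 significant
#' digits), so a write/read round trip is lossless. An audit header comment
#' records the package version and, optionally, digests of the input files
#' the table was derived from.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param input_digests Optional named character vector of input-file
#'   digests (e.g. from [tools::md5sum()]) recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, input_digests = NULL) {
  header <- paste0("# gariqc v",
                   as.character(utils::packageVersion("gariqc")))
  if (!is.null(input_digests)) {
    header <- c(header, paste0("# input ", names(input_digests), " md5=",
                               input_digests))
  }
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a two-column temperature trace CSV
#'
#' @param path CSV with columns `time_s`, `temp_K`.
#' @return A tibble with numeric `time_s` and `temp_K`.
#' @export
read_trace <- function(path) {
  read_trials(path, "trace")
}

#' Read a calorimeter run manifest and its trace files
#'
#' Loads the run manifest CSV (`calorimeter_runs.csv` as written by
#' [write_study_csvs()]) plus every referenced trace file and reassembles
#' the in-memory run objects consumed by [calibrate_calorimeter()] and
#' [reduce_calorimetry()].
#'
#' @param dir Directory containing the manifest and trace CSVs.
#' @param manifest_file Manifest file name within `dir`.
#' @return A list with `calibration_runs` and `sample_runs`.
#' @export
read_calorimeter_runs <- function(dir, manifest_file = "calorimeter_runs.csv") {
  manifest <- read_trials(file.path(dir, manifest_file), "manifest")
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    trace <- read_trace(file.path(dir, row$trace_file))
    run <- list(times_s = trace$time_s, temps_K = trace$temp_K,
                ignition_time_s = row$ignition_time_s, kind = row$kind)
    if (row$kind == "sample") {
      run$sample_id <- row$sample_id
      run$trial_id <- i
      run$sample_mass_g <- row$sample_mass_g
      run$fuel_mass_g <- row$fuel_mass_g
    } else {
      run$benzoic_mass_g <- row$benzoic_mass_g
      run$benzoic_gcv_J_per_g <- row$benzoic_gcv_J_per_g
    }
    run
  })
  kinds <- vapply(runs, `[[`, "", "kind")
  list(calibration_runs = runs[kinds == "calibration"],
       sample_runs = runs[kinds == "sample"])
}

#' Write a simulated study to a directory of CSV files
#'
#' Materialises the in-memory raw dataset of [simulate_study()] as the CSV
#' schemas the readers consume: one file per scalar assay, one sieve-trial
#' file, a calorimeter run manifest, and one trace file per firing.
#'
#' @param raw A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csvs <- function(raw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(raw$sieve_trials, file.path(dir, "sieve_trials.csv"))
  for (a in c("density", "swelling", "moisture", "cyanide", "acidity")) {
    write_table(raw[[a]], file.path(dir, paste0(a, ".csv")))
  }
  runs <- c(raw$calibration_runs, raw$sample_runs)
  manifest <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    tibble::tibble(
      run_id = sprintf("run%03d", i),
      kind = r$kind,
      sample_id = if (is.null(r$sample_id)) NA_character_ else r$sample_id,
      ignition_time_s = r$ignition_time_s,
      sample_mass_g = if (is.null(r$sample_mass_g)) NA_real_ else r$sample_mass_g,
      fuel_mass_g = if (is.null(r$fuel_mass_g)) NA_real_ else r$fuel_mass_g,
      benzoic_mass_g = if (is.null(r$benzoic_mass_g)) NA_real_ else r$benzoic_mass_g,
      benzoic_gcv_J_per_g = if (is.null(r$benzoic_gcv_J_per_g)) NA_real_
                            else r$benzoic_gcv_J_per_g,
      trace_file = sprintf("trace_run%03d.csv", i)
    )
  }))
  write_table(manifest, file.path(dir, "calorimeter_runs.csv"))
  for (i in seq_along(runs)) {
    write_table(
      tibble::tibble(time_s = runs[[i]]$times_s, temp_K = runs[[i]]$temps_K),
      file.path(dir, sprintf("trace_run%03d.csv", i))
    )
  }
  invisible(dir)
}

#' Aggregate per-trial results into per-sample summaries
#'
#' Collapses a long table of per-trial parameter values into the per-sample
#' arithmetic mean, sample (n-1) standard deviation (`NA` for a single
#' trial), and replicate count, via [average_over_trials()].
#'
#' @param per_trial Long tibble with columns `sample_id`, `parameter`,
#'   `value` (one row per trial).
#' @return A tibble with one row per (sample, parameter): columns
#'   `sample_id`, `parameter`, `mean`, `sd`, `n`.
#' @export
aggregate_results <- function(per_trial) {
  stopifnot(all(c("sample_id", "parameter", "value") %in% names(per_trial)))
  per_trial |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$sample_id, .data$parameter) |>
    dplyr::summarise(
      mean = average_over_trials(.data$value)$mean,
      sd = average_over_trials(.data$value)$sd,
      n = length(.data$value),
      .groups = "drop"
    )
}
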