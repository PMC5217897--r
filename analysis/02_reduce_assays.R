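#!/usr/bin/env Rscript
# Reduce the non-calorimetric raw readings to per-trial quality parameters:
# granulometry (median + weighted mean diameter), bulk density, swelling
# index, moisture, photometric cyanide, and moisture-corrected acidity.

library(gariqc)
suppressPackageStartupMessages(library(dplyr))

spec <- sieve_spec()

gran <- reduce_granulometry(read_trials("results/raw/sieve_trials.csv",
                                        "sieve"), spec)
write_table(gran, "results/granulometry_per_trial.csv")

density <- read_trials("results/raw/density.csv", "density") |>
  mutate(bulk_density_g_cm3 = bulk_density(sample_mass_g, tapped_volume_cm3))
swelling <- read_trials("results/raw/swelling.csv", "swelling") |>
  mutate(swelling_index = swelling_index(initial_volume_ml,
                                         swollen_volume_ml))
moisture <- read_trials("results/raw/moisture.csv", "moisture") |>
  mutate(moisture_percent = 100 * moisture_content(fresh_weight_g,
                                                   dry_weight_g))
cyanide <- read_trials("results/raw/cyanide.csv", "cyanide") |>
  mutate(cyanide_ppm = cyanide_ppm(absorbance_510nm, sample_mass_mg,
                                   elution_volume_ml))

# acidity uses each sample's mean moisture for the dry-matter correction
h_mean <- moisture |>
  group_by(sample_id) |>
  summarise(h = mean(moisture_percent) / 100)
acidity <- read_trials("results/raw/acidity.csv", "acidity") |>
  left_join(h_mean, by = "sample_id") |>
  mutate(acidity_g_per_100g = corrected_tta(titration_volume_ml, h))

for (nm in c("density", "swelling", "moisture", "cyanide", "acidity")) {
  write_table(get(nm), paste0("results/", nm, "_per_trial.csv"))
}

cat("Per-trial reductions written to results/*_per_trial.csv\n")
cat("  grain size: median", round(min(gran$median_um)), "-",
    round(max(gran$median_um)), "um across",
    nrow(gran), "trials\n")
cat("  moisture:", round(min(moisture$moisture_percent), 2), "-",
    round(max(moisture$moisture_percent), 2), "%\n")
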