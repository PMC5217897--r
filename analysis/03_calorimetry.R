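#!/usr/bin/env Rscript
# Reduce the bomb-calorimeter traces: calibrate the calorimeter constant
# from the benzoic-acid firings, then compute each sample firing's gross
# calorific value net of spiking fuel and ignition wire.

library(gariqc)

cfg <- calorimeter_config()
runs <- read_calorimeter_runs("results/raw")

cal <- calibrate_calorimeter(runs$calibration_runs, cfg)
write_table(cal$per_run, "results/calorimeter_calibration.csv")
cat("Calorimeter constant:", round(cal$K_J_per_K, 1), "J/K (mean of",
    nrow(cal$per_run), "benzoic-acid firings)\n")

gcv <- reduce_calorimetry(runs$sample_runs, cfg, cal$K_J_per_K)
write_table(gcv, "results/calorimetry_per_trial.csv")
cat("Gross calorific values:", round(min(gcv$gcv_kJ_g), 2), "-",
    round(max(gcv$gcv_kJ_g), 2), "kJ/g over", nrow(gcv), "firings\n")
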