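#!/usr/bin/env Rscript
# Generate the raw laboratory readings of the 14-sample demonstration study
# and materialise them as CSVs under results/raw/.
#
# Every downstream driver works only from these files, mirroring a field
# campaign in which each instrument produces its own delimited log.

library(gariqc)

seed <- 20260924
raw <- simulate_study(togo_maritime_truths(), seed = seed)
write_study_csvs(raw, "results/raw")
write_table(raw$truths, "results/raw/truths.csv")

cat("Simulated study (seed", seed, "):\n")
cat(" ", nrow(raw$truths), "samples;",
    nrow(raw$sieve_trials) / nrow(sieve_spec()$classes), "sieve trials;",
    length(raw$sample_runs), "calorimeter firings +",
    length(raw$calibration_runs), "calibrations\n")
cat("  raw CSVs written to results/raw/\n")
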