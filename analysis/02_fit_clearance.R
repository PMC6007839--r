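#!/usr/bin/env Rscript
# Fit every simulated tear trace to the zero-plateau single-exponential
# clearance model, apply quality control, and compare fitted kinetics
# against the hidden truth from 01_simulate_cohort.R.

library(fluoroperm)

protocol <- read_protocol(system.file("extdata", "protocol_default.yaml",
                                      package = "fluoroperm"))
sim <- generate_cohort(truth_config(seed = 1), protocol)  # same seed as 01

fits <- lapply(sim$traces, fit_decay)
qc <- lapply(fits, qc_fit)

tab <- data.frame(
  eye_id = names(fits),
  f0_mV = sapply(fits, `[[`, "f0_mV"),
  kd_per_s = sapply(fits, `[[`, "kd_per_s"),
  half_life_s = sapply(fits, `[[`, "half_life_s"),
  r_squared = sapply(fits, `[[`, "r_squared"),
  qc_pass = sapply(qc, `[[`, "pass"),
  true_kd_per_s = sim$truth$kd_per_s,
  true_f0dp_mV = sim$truth$f0dp_mV
)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/clearance_fits.csv", row.names = FALSE)

rel_kd <- abs(tab$kd_per_s - tab$true_kd_per_s) / tab$true_kd_per_s
cat(sprintf("Fitted %d traces; %d passed QC (R2 > 0.9, positive rate).\n",
            nrow(tab), sum(tab$qc_pass)))
cat(sprintf("Fitted kd: %.4f +/- %.4f /s (half-life %.0f-%.0f s)\n",
            mean(tab$kd_per_s), sd(tab$kd_per_s),
            min(tab$half_life_s), max(tab$half_life_s)))
cat(sprintf("Median relative error of kd vs truth: %.2f%%\n",
            100 * median(rel_kd)))
cat("Wrote results/clearance_fits.csv\n")
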