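#!/usr/bin/env Rscript
# Draw synthetic subjects and simulate landmark pixel measurements for both
# studies under the default noise model (0.5 px landmark jitter +
# pixel-grid quantization).

suppressPackageStartupMessages(library(facefd))
dir.create("results", showWarnings = FALSE)

for (cfg in list(dslr_study_config(), smartphone_study_config())) {
  design <- study_design(cfg)
  subjects <- sample_subjects(cfg$n_participants, cfg$priors,
                              cfg$pcs_mean_mm, cfg$pcs_sd_mm,
                              seed = cfg$seed + 1L)
  meas <- simulate_measurements(design, subjects, cfg$cameras, cfg$noise,
                                seed = cfg$seed + 2L)
  out <- sprintf("results/measurements_%s.csv", cfg$type)
  write_measurements(meas, out, seed = cfg$seed, config_hash = cfg$hash)
  message(sprintf(
    "%s study: %d subjects (PFL %.2f +/- %.2f mm), %d simulated photographs -> %s",
    cfg$type, nrow(subjects), mean(subjects$pfl_true_mm),
    stats::sd(subjects$pfl_true_mm), nrow(meas), out
  ))
}
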