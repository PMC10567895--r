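#!/usr/bin/env Rscript
# Estimate the focus distance of every simulated photograph: frontal views
# from the palpebral fissure length, profile views through the
# frontal-calibrated pupil-chord-to-stomion chain.

suppressPackageStartupMessages(library(facefd))

for (cfg in list(dslr_study_config(), smartphone_study_config())) {
  meas <- read_measurements(sprintf("results/measurements_%s.csv", cfg$type))
  est <- add_fd_estimates(meas, cfg$cameras, cfg$priors, cfg$model_variant)
  out <- sprintf("results/estimates_%s.csv", cfg$type)
  write_estimates(est, out, seed = cfg$seed, config_hash = cfg$hash)
  pooled <- summarize_errors(est)
  message(sprintf(
    "%s study: %d estimates after best-replicate selection; pooled MSE %.0f mm, MAE %.0f mm, MAE%% %.2f%%, SEE %.0f mm -> %s",
    cfg$type, nrow(est), pooled$mse_mm, pooled$mae_mm, pooled$mae_pct,
    pooled$see_mm, out
  ))
}
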