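#!/usr/bin/env Rscript
# Measurement-error propagation: (a) the closed-form anatomical error floor
# of the known-length proxy, checked by Monte Carlo against quadrature;
# (b) the MAE% trend with focus distance under landmark jitter +
# quantization, at large simulated sample size.

suppressPackageStartupMessages({
  library(facefd)
  library(dplyr)
})
dir.create("results", showWarnings = FALSE)

## (a) anatomical floor: relative error is exactly A / PFL_true - 1
pri <- anatomical_priors()
cam <- dslr_camera_specs()$canon_6d_100mm
subjects <- sample_subjects(1e5, pri, seed = 31)
est <- estimate_fd_frontal(project_length(subjects$pfl_true_mm, 3000, cam),
                           cam, pri)$fd_mm
mc <- error_metrics(est, rep(3000, nrow(subjects)))
A <- pri$mean_pfl_mm; s <- pri$sd_pfl_mm
f <- function(p) abs(A / p - 1) * 100 * stats::dnorm(p, A, s)
quad <- stats::integrate(f, A / 2, A, rel.tol = 1e-10)$value +
  stats::integrate(f, A, 2 * A, rel.tol = 1e-10)$value
message(sprintf(
  "Anatomical error floor: Monte-Carlo MAE%% %.3f%% vs quadrature %.3f%% (noiseless pixels; PFL ~ N(%.1f, %.1f) mm).",
  mc$mae_pct, quad, A, s
))

## (b) MAE% vs distance at 100k participants per body
cfg <- dslr_study_config()
trend_subjects <- sample_subjects(1e5, cfg$priors, cfg$pcs_mean_mm,
                                  cfg$pcs_sd_mm, seed = 32)
summaries <- list()
for (body in cfg$bodies$name) {
  design <- build_dslr_design(1e5, body, cfg$lens_configs, replicates = 1)
  meas <- simulate_measurements(design, trend_subjects, cfg$cameras,
                                cfg$noise, seed = 33)
  estb <- add_fd_estimates(meas, cfg$cameras, cfg$priors)
  summaries[[body]] <- summarize_errors(
    estb, group_by = c("camera_body", "lens_label", "distance_mm"))
  rm(design, meas, estb); gc(verbose = FALSE)
}
trend <- bind_rows(summaries) |> arrange(camera_body, lens_label, distance_mm)
write_estimates(trend, "results/mae_trend_dslr.csv", seed = 32, config_hash = cfg$hash)

wide <- trend |>
  group_by(camera_body, lens_label) |>
  summarise(mae_1m = mae_pct[distance_mm == 1000],
            mae_10m = mae_pct[distance_mm == 10000],
            monotone = all(diff(mae_pct) >= 0), .groups = "drop")
message(sprintf(
  "MAE%% grows with distance in %d/%d camera/lens combinations; 24 mm wide-angle reaches %.1f%% at 10 m (vs ~%.1f%% anatomical floor).",
  sum(wide$monotone), nrow(wide),
  max(trend$mae_pct[trend$lens_label == "zoom_min" & trend$distance_mm == 10000]),
  quad
))
message("Wrote results/mae_trend_dslr.csv")
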