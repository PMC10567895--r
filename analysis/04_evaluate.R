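#!/usr/bin/env Rscript
# Grouped validation statistics and perspective-tolerance tables, plus
# signed-error-vs-distance figures per camera/lens.

suppressPackageStartupMessages({
  library(facefd)
  library(dplyr)
})

for (cfg in list(dslr_study_config(), smartphone_study_config())) {
  est <- read_measurements(sprintf("results/estimates_%s.csv", cfg$type))
  est$fd_est_mm <- as.numeric(est$fd_est_mm)

  summ <- summarize_errors(est, group_by = cfg$group_by)
  write_estimates(summ, sprintf("results/summary_%s.csv", cfg$type),
                  seed = cfg$seed, config_hash = cfg$hash)

  tol <- tolerance_table(est, cfg$depth_model, cfg$threshold_pct,
                         group_by = c("camera_body", "lens_label", "distance_mm"))
  write_estimates(tol, sprintf("results/tolerance_%s.csv", cfg$type),
                  seed = cfg$seed, config_hash = cfg$hash)

  by_dist <- summarize_errors(est, group_by = c("lens_label", "distance_mm"))
  worst <- by_dist |> slice_max(mae_pct, n = 1)
  message(sprintf(
    "%s study: %d summary groups; %d/%d station groups fully inside the %.3g%% facial-height tolerance; worst cell: %s at %.1f m (MAE%% %.1f%%).",
    cfg$type, nrow(summ), sum(tol$all_pass), nrow(tol), cfg$threshold_pct,
    worst$lens_label, worst$distance_mm / 1000, worst$mae_pct
  ))

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    library(ggplot2)
    p <- summarize_errors(est, group_by = c("camera_body", "lens_label",
                                            "view", "distance_mm")) |>
      ggplot(aes(distance_mm / 1000, mse_mm, colour = lens_label,
                 linetype = view)) +
      geom_hline(yintercept = 0, colour = "grey60") +
      geom_line() + geom_point(size = 0.8) +
      facet_wrap(~camera_body) +
      labs(x = "ground-truth focus distance (m)", y = "mean signed error (mm)",
           colour = "lens / camera", linetype = "view") +
      theme_minimal()
    ggsave(sprintf("results/signed_error_%s.pdf", cfg$type), p,
           width = 9, height = 4)
    message(sprintf("Wrote results/signed_error_%s.pdf", cfg$type))
  }
}
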