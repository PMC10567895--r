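test_that("synthetic subjects reproduce the anatomical prior distribution", {
  pri <- priors30()
  s1 <- sample_subjects(100, pri, seed = 5)
  s2 <- sample_subjects(100, pri, seed = 5)
  expect_identical(s1, s2) # same seed, same subjects
  expect_false(identical(s1, sample_subjects(100, pri, seed = 6)))
  expect_identical(s1$subject_id, 1:100)

  big <- sample_subjects(1e5, pri, seed = 11)
  expect_gt(stats::sd(big$pfl_true_mm), 1.18)
  expect_lt(stats::sd(big$pfl_true_mm), 1.22)
  expect_equal(mean(big$pfl_true_mm), 30, tolerance = 1e-3)

  degenerate <- sample_subjects(20, priors30(sd = 0), seed = 1)
  expect_true(all(degenerate$pfl_true_mm == 30))
})

test_that("non-positive anatomical draws are redrawn", {
  # mean barely above the SD: naive normal draws would often be negative
  pri <- anatomical_priors(2, 1.9)
  s <- sample_subjects(5000, pri, pcs_mean_mm = 2, pcs_sd_mm = 1.9, seed = 3)
  expect_true(all(s$pfl_true_mm > 0))
  expect_true(all(s$pcs_true_mm > 0))
})

test_that("sampling leaves the global RNG state untouched", {
  withr::with_seed(99, {
    before <- .Random.seed
    sample_subjects(10, priors30(), seed = 123)
    expect_identical(.Random.seed, before)
  })
})

test_that("noise-free measurements recover ground truth end-to-end", {
  cfg <- dslr_study_config()
  subjects <- sample_subjects(3, priors30(sd = 0), pcs_sd_mm = 0, seed = 1)
  design <- build_dslr_design(3, "canon_6d", cfg$lens_configs)
  meas <- simulate_measurements(design, subjects, cfg$cameras,
                                noise_model(0, quantize = FALSE))
  est <- add_fd_estimates(meas, cfg$cameras, priors30())
  expect_true(all(abs(est$fd_est_mm - est$fd_true_mm) / est$fd_true_mm < 1e-12))
})

test_that("quantization alone degrades wide-angle long-FD estimates", {
  # uses the study-default priors: quantize-only error depends on where the
  # population-mean pixel length falls on the pixel grid (see the vignette
  # on quantization aliasing), and the default A = 30.7 mm sits mid-grid
  # for this camera at 10 m
  cfg <- dslr_study_config()
  subjects <- sample_subjects(300, cfg$priors, seed = 21)
  lens24 <- list(canon_6d = tibble::tibble(lens_label = "zoom_min", focal_length_mm = 24))
  design <- build_dslr_design(300, "canon_6d", lens24,
                              distances_mm = c(1000, 10000), replicates = 1)
  meas <- simulate_measurements(design, subjects, cfg$cameras,
                                noise_model(0, quantize = TRUE), seed = 22)
  # pixel lengths at 10 m with a 24 mm lens are small integers
  far <- meas[meas$fd_true_mm == 10000 & meas$view == "frontal", ]
  expect_true(all(far$pfl_px == round(far$pfl_px)))
  expect_lt(max(far$pfl_px), 20)

  est <- add_fd_estimates(meas, cfg$cameras, cfg$priors)
  s <- summarize_errors(est, group_by = "distance_mm")
  expect_gt(s$mae_pct[s$distance_mm == 10000], s$mae_pct[s$distance_mm == 1000])
})

test_that("measurement simulation is reproducible and seed-sensitive", {
  cfg <- smartphone_study_config()
  subjects <- sample_subjects(2, priors30(), seed = 8)
  design <- build_smartphone_design(2, dropouts = NULL)
  m1 <- simulate_measurements(design, subjects, cfg$cameras, noise_model(), seed = 9)
  m2 <- simulate_measurements(design, subjects, cfg$cameras, noise_model(), seed = 9)
  expect_identical(m1, m2)
  m3 <- simulate_measurements(design, subjects, cfg$cameras, noise_model(), seed = 10)
  expect_false(identical(m1, m3))

  # frontal rows carry both landmark lengths, profile rows only pcs
  expect_true(all(is.na(m1$pfl_px[m1$view == "profile"])))
  expect_true(all(!is.na(m1$pfl_px[m1$view == "frontal"])))
  expect_true(all(!is.na(m1$pcs_px)))
})

test_that("landmark jitter has the configured pixel-scale spread", {
  cfg <- dslr_study_config()
  subjects <- sample_subjects(1, priors30(sd = 0), pcs_sd_mm = 0, seed = 2)
  design <- build_dslr_design(1, "canon_6d",
                              list(canon_6d = tibble::tibble(lens_label = "prime_100",
                                                             focal_length_mm = 100)),
                              distances_mm = 2000, views = "frontal", replicates = 1)
  design <- design[rep(1, 4000), ]
  design$replicate <- seq_len(nrow(design))
  clean <- simulate_measurements(design, subjects, cfg$cameras,
                                 noise_model(0, FALSE))
  noisy <- simulate_measurements(design, subjects, cfg$cameras,
                                 noise_model(0.5, FALSE), seed = 13)
  resid <- noisy$pfl_px - clean$pfl_px
  expect_equal(stats::sd(resid), 0.5, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 0.05)
})

test_that("unresolvable design references are config errors", {
  cfg <- dslr_study_config()
  subjects <- sample_subjects(2, priors30(), seed = 1)
  design <- build_dslr_design(3, "canon_6d", cfg$lens_configs) # participant 3 unknown
  expect_error(simulate_measurements(design, subjects, cfg$cameras),
               "unknown participant")
  design2 <- build_dslr_design(2, "canon_6d", cfg$lens_configs)
  expect_error(simulate_measurements(design2, subjects, cfg$cameras["canon_6d_50mm"]),
               "no camera specification")
})

test_that("projected pixel lengths never grow with focus distance", {
  cfg <- dslr_study_config()
  subjects <- sample_subjects(5, priors30(), seed = 31)
  design <- build_dslr_design(5, "nikon_d780", cfg$lens_configs, replicates = 1)
  meas <- simulate_measurements(design, subjects, cfg$cameras,
                                noise_model(0, FALSE))
  ordered <- dplyr::arrange(meas, subject_id, camera_name, view, fd_true_mm)
  by_series <- split(ordered$pcs_px,
                     paste(ordered$subject_id, ordered$camera_name, ordered$view))
  expect_true(all(vapply(by_series, function(x) all(diff(x) < 0), logical(1))))
})
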