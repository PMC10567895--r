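test_that("anatomical priors are validated", {
  pri <- anatomical_priors()
  expect_equal(pri$sd_pfl_mm, 1.2)
  expect_error(anatomical_priors(-30), "mean_pfl_mm")
  expect_error(anatomical_priors(30, -1), "non-negative")
  expect_error(anatomical_priors(30, 31), "smaller than")
  expect_silent(anatomical_priors(30, 0))
})

test_that("frontal estimates invert the projection", {
  cam <- demo_camera()
  pri <- priors30()
  est <- estimate_fd_frontal(200, cam, pri)
  expect_s3_class(est, "fd_estimate")
  expect_equal(est$fd_mm, 3000)
  expect_identical(est$view, "frontal")
  expect_identical(est$model_variant, "simple")
  expect_equal(est$inputs$known_length_mm, 30)

  # halving law: doubling the measured pixels halves the estimate
  expect_equal(estimate_fd_frontal(400, cam, pri)$fd_mm, 1500)
  # Canon 6D pitch round trip
  expect_equal(estimate_fd_frontal(3000 / 6.55, canon_6d_100(), pri)$fd_mm,
               1000, tolerance = 1e-12)

  expect_error(estimate_fd_frontal(0, cam, pri), "invalid measurement")
  expect_error(estimate_fd_frontal(-5, cam, pri), "invalid measurement")
})

test_that("projection and estimation are exact inverses across all fixture cameras", {
  pri <- priors30()
  cams <- c(dslr_camera_specs(), smartphone_camera_specs())
  fds <- seq(200, 10000, by = 490)
  for (cam in cams) {
    ok <- fds > cam$focal_length_mm
    px <- project_length(30, fds[ok], cam)
    expect_equal(estimate_fd_frontal(px, cam, pri)$fd_mm, fds[ok], tolerance = 1e-12)

    ok_tl <- fds > 4 * cam$focal_length_mm
    px_tl <- project_length(30, fds[ok_tl], cam, "thin_lens")
    expect_equal(estimate_fd_frontal(px_tl, cam, pri, "thin_lens")$fd_mm,
                 fds[ok_tl], tolerance = 1e-9)
  }
})

test_that("thin-lens estimation rejects magnification >= 1", {
  cam <- demo_camera()
  # pfl_px * y >= A means the image is at least life size
  expect_error(estimate_fd_frontal(30 / 0.005, cam, priors30(), "thin_lens"),
               "magnification")
  est <- estimate_fd_frontal(200, cam, priors30(), "thin_lens")
  expect_gt(est$fd_mm, cam$focal_length_mm)
})

test_that("the frontal-calibrated scale transfer is the prior-ratio rule", {
  pri <- priors30()
  expect_equal(estimate_pcs_mm_from_frontal(200, 400, pri), 60)
  expect_equal(estimate_pcs_mm_from_frontal(200, 200, pri), 30)
  # linear in pcs_px
  expect_equal(estimate_pcs_mm_from_frontal(200, c(100, 300), pri), c(15, 45))
  expect_error(estimate_pcs_mm_from_frontal(0, 400, pri), "invalid measurement")
  expect_error(estimate_pcs_mm_from_frontal(200, -1, pri), "invalid measurement")

  # noiseless subject whose true PFL equals the prior mean: the recovered
  # pcs length is the subject's true value exactly
  cam <- demo_camera()
  pfl_px <- project_length(30, 2700, cam)
  pcs_px <- project_length(64.2, 2700, cam)
  expect_equal(estimate_pcs_mm_from_frontal(pfl_px, pcs_px, pri), 64.2,
               tolerance = 1e-12)
})

test_that("profile estimates mirror the frontal inversion", {
  cam <- demo_camera()
  est <- estimate_fd_profile(400, 60, cam)
  expect_equal(est$fd_mm, 3000)
  expect_identical(est$view, "profile")
  expect_equal(estimate_fd_profile(800, 60, cam)$fd_mm, 1500) # doubling halves
  expect_error(estimate_fd_profile(0, 60, cam), "invalid measurement")
  expect_error(estimate_fd_profile(400, -2, cam), "invalid measurement")
})

test_that("noiseless frontal/profile pairs agree regardless of subject anatomy", {
  cam <- canon_6d_100()
  pri <- priors30()
  withr::with_seed(42, {
    for (i in 1:50) {
      fd <- runif(1, 500, 10000)
      pfl <- rnorm(1, 30, 1.2)
      pcs <- rnorm(1, 65, 3.5)
      pair <- noiseless_pair(fd, pfl, pcs, cam)
      res <- estimate_pair(pair$frontal, pair$profile, cam, pri)
      expect_equal(res$profile$fd_mm, res$frontal$fd_mm, tolerance = 1e-12)
      # both reduce to fd * A / PFL_true
      expect_equal(res$frontal$fd_mm, fd * 30 / pfl, tolerance = 1e-12)
    }
  })
})

test_that("pair estimation validates camera identity and required fields", {
  cam <- demo_camera()
  pri <- priors30()
  pair <- noiseless_pair(3000, 30, 60, cam)
  res <- estimate_pair(pair$frontal, pair$profile, cam, pri)
  expect_equal(res$frontal$fd_mm, 3000, tolerance = 1e-12)
  expect_equal(res$profile$fd_mm, 3000, tolerance = 1e-12)
  expect_equal(res$pcs_mm_est, 60, tolerance = 1e-12)

  other <- pair$profile
  other$camera_name <- "different_cam"
  expect_error(estimate_pair(pair$frontal, other, cam, pri), "pairing error")
  # a frontal-only pair (profile row missing its pixel length)
  noprofile <- pair$profile
  noprofile$pcs_px <- NA_real_
  expect_error(estimate_pair(pair$frontal, noprofile, cam, pri), "invalid measurement")
  nofrontal <- pair$frontal
  nofrontal$pfl_px <- NA_real_
  expect_error(estimate_pair(nofrontal, pair$profile, cam, pri), "invalid measurement")

  # subject one SD longer than the prior mean: closed-form propagation
  pair2 <- noiseless_pair(3000, 31.2, 65, cam)
  res2 <- estimate_pair(pair2$frontal, pair2$profile, cam, pri)
  expect_equal(res2$frontal$fd_mm, 3000 * 30 / 31.2, tolerance = 1e-12)
  expect_equal(res2$profile$fd_mm, 3000 * 30 / 31.2, tolerance = 1e-12)
})

test_that("with noiseless pixels the signed relative error is the anatomical ratio", {
  cam <- canon_6d_100()
  pri <- priors30()
  withr::with_seed(7, pfls <- rnorm(200, 30, 1.2))
  fd <- 4000
  px <- project_length(pfls, fd, cam)
  est <- estimate_fd_frontal(px, cam, pri)$fd_mm
  expect_equal((est - fd) / fd, 30 / pfls - 1, tolerance = 1e-12)
})

test_that("estimates strictly decrease as measured pixel lengths increase", {
  cam <- demo_camera()
  pri <- priors30()
  px <- seq(20, 2000, length.out = 100)
  expect_true(all(diff(estimate_fd_frontal(px, cam, pri)$fd_mm) < 0))
  expect_true(all(diff(estimate_fd_frontal(px, cam, pri, "thin_lens")$fd_mm) < 0))
  expect_true(all(diff(estimate_fd_profile(px, 60, cam)$fd_mm) < 0))
})
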