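test_that("error metrics match their definitions on worked cases", {
  m <- error_metrics(c(1100, 900), c(1000, 1000))
  expect_equal(m$mse_mm, 0) # signed errors cancel
  expect_equal(m$mae_mm, 100)
  expect_equal(m$mae_pct, 10)
  expect_equal(m$see_mm, 100)
  expect_equal(m$n, 2L)

  exact <- error_metrics(c(500, 2500, 9000), c(500, 2500, 9000))
  expect_equal(unlist(exact[c("mse_mm", "mae_mm", "mae_pct", "see_mm")]),
               c(mse_mm = 0, mae_mm = 0, mae_pct = 0, see_mm = 0))

  expect_error(error_metrics(numeric(0), numeric(0)), "non-empty")
  expect_error(error_metrics(1:3, 1:2), "equal length")
  expect_error(error_metrics(c(1, 2), c(1, -2)), "positive")
  expect_error(error_metrics(c(1, NA), c(1, 2)), "finite")
})

test_that("error metrics agree with a brute-force recomputation", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(2:50, 1)
      truth <- runif(n, 200, 10000)
      est <- truth * (1 + rnorm(n, 0, 0.1))
      m <- error_metrics(est, truth)
      # independent one-line recomputations
      expect_equal(m$mse_mm, sum(est - truth) / n, tolerance = 1e-12)
      expect_equal(m$mae_mm, sum(abs(est - truth)) / n, tolerance = 1e-12)
      expect_equal(m$mae_pct, 100 * sum(abs(est / truth - 1)) / n, tolerance = 1e-12)
      expect_equal(m$see_mm, sqrt(mean((est - truth)^2)), tolerance = 1e-12)
      expect_lte(abs(m$mse_mm), m$mae_mm)
      expect_lte(m$mae_mm, m$see_mm) # Cauchy-Schwarz
      # regression-convention denominator
      m2 <- error_metrics(est, truth, see_denominator = "n-2")
      expect_equal(m2$see_mm, sqrt(sum((est - truth)^2) / (n - 2)), tolerance = 1e-12)
    }
  })
})

test_that("grouped summaries decompose consistently", {
  withr::with_seed(23, {
    df <- tibble::tibble(
      g = rep(c("a", "b"), c(30, 50)),
      fd_true_mm = runif(80, 500, 8000)
    )
    df$fd_est_mm <- df$fd_true_mm * (1 + rnorm(80, 0, 0.05))
  })
  pooled <- summarize_errors(df)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled, error_metrics(df$fd_est_mm, df$fd_true_mm)[names(pooled)])

  grouped <- summarize_errors(df, group_by = "g")
  expect_equal(nrow(grouped), 2)
  # pooled mean signed error is the n-weighted mean of group values
  expect_equal(sum(grouped$n * grouped$mse_mm) / sum(grouped$n), pooled$mse_mm,
               tolerance = 1e-12)
  expect_equal(sum(grouped$n * grouped$mae_mm) / sum(grouped$n), pooled$mae_mm,
               tolerance = 1e-12)

  # grouping by a constant column yields one row; row order is irrelevant
  df$const <- "all"
  expect_equal(nrow(summarize_errors(df, group_by = "const")), 1)
  shuffled <- df[sample(nrow(df)), ]
  expect_equal(summarize_errors(shuffled, group_by = "g"), grouped)

  expect_error(summarize_errors(df, group_by = "nope"), "unknown group key")
})

test_that("metrics rescale consistently with units", {
  withr::with_seed(29, {
    truth <- runif(40, 1000, 9000)
    est <- truth + rnorm(40, 50, 200)
  })
  mm <- error_metrics(est, truth)
  m <- error_metrics(est / 1000, truth / 1000)
  expect_equal(m$mse_mm, mm$mse_mm / 1000)
  expect_equal(m$mae_mm, mm$mae_mm / 1000)
  expect_equal(m$see_mm, mm$see_mm / 1000)
  expect_equal(m$mae_pct, mm$mae_pct) # percent error is unit-free
})

test_that("systematic underestimation yields negative mean signed error", {
  truth <- c(2000, 3000, 4000)
  low <- error_metrics(truth * 0.8, truth)
  expect_lt(low$mse_mm, 0)
  expect_equal(low$mae_mm, abs(low$mse_mm)) # one-sided errors
})

test_that("tolerance tables flag exactly the offending groups", {
  dm <- face_depth_model(100)
  df <- tibble::tibble(
    station = rep(c("s1", "s2", "s3"), each = 4),
    fd_true_mm = rep(c(1000, 2000, 4000), each = 4)
  )
  df$fd_est_mm <- df$fd_true_mm
  tab <- tolerance_table(df, dm, group_by = "station")
  expect_equal(tab$pass_fraction, c(1, 1, 1))
  expect_true(all(tab$all_pass))
  expect_equal(nrow(tab), 3) # complete grid, all-pass groups included

  # inject one violation (change > 1%) at one station
  df$fd_est_mm[1] <- 850
  expect_gt(facial_height_change_pct(1000, 850, dm), 1)
  tab2 <- tolerance_table(df, dm, group_by = "station")
  expect_equal(sum(!tab2$all_pass), 1)
  expect_equal(tab2$pass_fraction[tab2$station == "s1"], 0.75)
  expect_equal(sum(tab2$n), 12)
})

test_that("simulated-study summaries satisfy the metric inequalities", {
  res <- run_pipeline(dslr_study_config(), seed = 3, quiet = TRUE)
  s <- res$summary
  expect_true(all(abs(s$mse_mm) <= s$mae_mm + 1e-12))
  expect_true(all(s$mae_mm <= s$see_mm + 1e-12))
  expect_true(all(s$mae_pct >= 0) && all(s$see_mm >= 0) && all(s$n >= 1))
})
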