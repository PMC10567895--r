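# Validation error statistics over (estimate, ground truth) pairs.

#' Error statistics for focus-distance estimates
#'
#' Computes, over paired estimates and ground truths (both mm):
#' * `mse_mm` - mean *signed* error, `mean(est - true)` (sign-preserving,
#'   not a squared error; systematic underestimation yields a negative
#'   value);
#' * `mae_mm` - mean absolute error;
#' * `mae_pct` - mean of per-observation absolute percent errors,
#'   `mean(100 * |est - true| / true)` (not MAE divided by the mean truth);
#' * `see_mm` - standard error of the estimate, `sqrt(sum((est-true)^2)/n)`
#'   by default (an RMSE about the ground truth; no regression is fitted,
#'   so the `n` denominator is the defensible default). The
#'   regression-convention `n - 2` denominator is available via
#'   `see_denominator = "n-2"`.
#'
#' @param estimates_mm,truths_mm Equal-length numeric vectors; truths must
#'   be positive.
#' @param see_denominator `"n"` (default) or `"n-2"`.
#' @return A one-row tibble with columns `n`, `mse_mm`, `mae_mm`,
#'   `mae_pct`, `see_mm`.
#' @export
#' @examples
#' error_metrics(c(1100, 900), c(1000, 1000))
error_metrics <- function(estimates_mm, truths_mm, see_denominator = c("n", "n-2")) {
  see_denominator <- match.arg(see_denominator)
  n <- length(estimates_mm)
  if (n == 0L || length(truths_mm) != n) {
    stop("estimates_mm and truths_mm must be non-empty and of equal length", call. = FALSE)
  }
  if (any(!is.finite(truths_mm)) || any(truths_mm <= 0)) {
    stop("truths_mm must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(estimates_mm))) {
    stop("estimates_mm must be finite (drop missing estimates first)", call. = FALSE)
  }
  denom <- if (see_denominator == "n") n else {
    if (n <= 2) stop("see_denominator = \"n-2\" needs n > 2", call. = FALSE)
    n - 2
  }
  e <- estimates_mm - truths_mm
  tibble::tibble(
    n = n,
    mse_mm = mean(e),
    mae_mm = mean(abs(e)),
    mae_pct = mean(100 * abs(e) / truths_mm),
    see_mm = sqrt(sum(e^2) / denom)
  )
}

check_group_keys <- function(x, group_by) {
  unknown <- setdiff(group_by, names(x))
  if (length(unknown)) {
    stop("config error: unknown group key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
}

drop_missing_estimates <- function(x, est_col, true_col) {
  keep <- is.finite(x[[est_col]]) & is.finite(x[[true_col]])
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing estimates or truths")
  }
  x[keep, , drop = FALSE]
}

#' Grouped error summaries
#'
#' One [error_metrics()] row per group of an estimates table. Rows with
#' missing estimates or truths are dropped with a message. Metrics are
#' invariant to row order; groups are emitted in deterministic (sorted)
#' order.
#'
#' @param estimates A data frame containing the estimate and truth columns
#'   plus any grouping columns.
#' @param group_by Character vector of grouping columns (may be empty: one
#'   pooled row).
#' @param est_col,true_col Column names (defaults `fd_est_mm`,
#'   `fd_true_mm`).
#' @inheritParams error_metrics
#' @return A tibble with the group keys, `n`, `mse_mm`, `mae_mm`,
#'   `mae_pct`, `see_mm`.
#' @export
summarize_errors <- function(estimates, group_by = character(),
                             est_col = "fd_est_mm", true_col = "fd_true_mm",
                             see_denominator = c("n", "n-2")) {
  see_denominator <- match.arg(see_denominator)
  check_group_keys(estimates, c(group_by, est_col, true_col))
  x <- drop_missing_estimates(estimates, est_col, true_col)
  if (nrow(x) == 0L) stop("no complete (estimate, truth) pairs to summarize", call. = FALSE)
  if (any(x[[true_col]] <= 0)) stop("truths must be positive", call. = FALSE)
  x$.err <- x[[est_col]] - x[[true_col]]
  x$.true <- x[[true_col]]
  denom <- function(n) if (see_denominator == "n") n else n - 2
  out <- dplyr::summarise(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(group_by))),
    n = dplyr::n(),
    mse_mm = mean(.err),
    mae_mm = mean(abs(.err)),
    mae_pct = mean(100 * abs(.err) / .true),
    see_mm = sqrt(sum(.err^2) / denom(dplyr::n())),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::across(dplyr::all_of(group_by)))
}

#' Grouped perspective-tolerance table
#'
#' For each group, the fraction of estimates whose implied change in
#' apparent facial height is within the tolerance
#' ([within_tolerance()]), plus an all-pass flag and the worst observed
#' change. Groups are emitted even when all of their estimates pass, so
#' the table is a complete grid.
#'
#' @inheritParams summarize_errors
#' @param depth_model A [face_depth_model()].
#' @param threshold_pct Tolerance on the facial-height change, percent
#'   (default 1).
#' @return A tibble with the group keys, `n`, `pass_fraction`, `all_pass`,
#'   `max_change_pct`.
#' @export
tolerance_table <- function(estimates, depth_model, threshold_pct = 1.0,
                            group_by = character(),
                            est_col = "fd_est_mm", true_col = "fd_true_mm") {
  check_scalar_pos(threshold_pct, "threshold_pct")
  check_group_keys(estimates, c(group_by, est_col, true_col))
  x <- drop_missing_estimates(estimates, est_col, true_col)
  if (nrow(x) == 0L) stop("no complete (estimate, truth) pairs to evaluate", call. = FALSE)
  x$.chg <- facial_height_change_pct(x[[true_col]], x[[est_col]], depth_model)
  out <- dplyr::summarise(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(group_by))),
    n = dplyr::n(),
    pass_fraction = mean(.chg <= threshold_pct),
    all_pass = all(.chg <= threshold_pct),
    max_change_pct = max(.chg),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::across(dplyr::all_of(group_by)))
}
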