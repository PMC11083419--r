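#' Intraclass correlation ICC(2,k): two-way, absolute agreement, mean of k raters
#'
#' Shrout-Fleiss ICC(2,k): every subject (row) is rated by the same k
#' raters (columns), agreement is absolute and the reported unit is the
#' mean of the k ratings. From the two-way ANOVA mean squares (rows MSR,
#' columns MSC, error MSE) the estimate is
#' \deqn{ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n).}
#' The 95% confidence interval is the McGraw & Wong (1996) F-based
#' interval for absolute-agreement average measures: the single-measure
#' interval with Satterthwaite degrees of freedom, stepped up to k
#' measures via the Spearman-Brown relation.
#'
#' Negative estimates or bounds are floored at 0 in the reported fields
#' (the convention used in reliability tables); the unclamped values are
#' kept in `$raw`.
#'
#' @param m Numeric matrix, subjects x raters, no missing cells,
#'   `nrow >= 3` (the CI needs at least 2 error df), `ncol >= 2`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `icc_result`: `estimate`, `ci_low`,
#'   `ci_high` (all clamped at 0), `raw` (unclamped triple), `ms_rows`,
#'   `ms_cols`, `ms_error`, `n`, `k`.
#' @examples
#' icc2k(cbind(r1 = c(1, 2, 3), r2 = c(2, 3, 4))) # estimate 0.8
#' @export
icc2k <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) abort("rating matrix must have no missing cells")
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("ICC(2,k) needs at least two raters")
  if (n < 3) abort("ICC(2,k) confidence intervals need at least 3 subjects")

  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_error / ((n - 1) * (k - 1))

  denom <- msr + (msc - mse) / n
  if (denom == 0) abort("zero total variance: ICC undefined")
  est <- (msr - mse) / denom

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # perfect agreement: interval degenerates to the point estimate
    ci <- c(est, est)
  } else {
    # single-measure absolute-agreement estimate and its F interval
    # (McGraw & Wong 1996, case A-1), then Spearman-Brown step-up to k
    icc_a1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse == 0) {
      # limit of the Satterthwaite df as MSC/MSE -> infinity
      v <- k - 1
    } else {
      fj <- msc / mse
      vn <- (k - 1) * (n - 1) *
        (k * icc_a1 * fj + n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2
      vd <- (n - 1) * k^2 * icc_a1^2 * fj^2 +
        (n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2
      v <- vn / vd
    }
    f_u <- qf(1 - alpha / 2, n - 1, v)
    f_l <- qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    ci <- c(l1 * k / (1 + l1 * (k - 1)), u1 * k / (1 + u1 * (k - 1)))
  }

  structure(list(
    estimate = max(0, est),
    ci_low = max(0, ci[1]),
    ci_high = max(0, ci[2]),
    raw = list(estimate = est, ci_low = ci[1], ci_high = ci[2]),
    ms_rows = msr, ms_cols = msc, ms_error = mse,
    n = n, k = k, conf_level = conf_level), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.3f  %g%% CI [%.3f, %.3f]  (n = %d)\n",
              x$k, x$estimate, 100 * x$conf_level, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Bland-Altman limits of agreement with Wald confidence intervals
#'
#' For paired measurements the inter-rater differences `d = r1 - r2` give
#' the bias `mean(d)` and the 95% limits of agreement
#' `bias +/- 1.96 sd(d)`. Wald 95% confidence intervals use
#' `1.96 sd / sqrt(n)` for the bias and `1.96 sd sqrt(3/n)` for each
#' limit (the large-sample standard error of a limit of agreement). The
#' z-multiplier 1.96 is fixed (Wald intervals), not a t quantile.
#'
#' @param m Numeric matrix, subjects x 2 raters, `nrow >= 2`.
#' @return An object of class `loa_result`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, and `ci_bias` / `ci_loa_low` / `ci_loa_high` (length-2
#'   vectors), plus `n`.
#' @examples
#' limits_of_agreement(cbind(c(1, 2, 3), c(2, 2, 2)))
#' @export
limits_of_agreement <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2) abort("limits of agreement are defined for exactly 2 raters")
  if (anyNA(m)) abort("rating matrix must have no missing cells")
  n <- nrow(m)
  if (n < 2) abort("limits of agreement need at least 2 paired measurements")
  d <- m[, 1] - m[, 2]
  bias <- mean(d)
  s <- sd(d)
  z <- 1.96
  loa <- bias + c(-1, 1) * z * s
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(list(
    bias = bias, sd_diff = s, loa_low = loa[1], loa_high = loa[2],
    ci_bias = bias + c(-1, 1) * z * se_bias,
    ci_loa_low = loa[1] + c(-1, 1) * z * se_loa,
    ci_loa_high = loa[2] + c(-1, 1) * z * se_loa,
    n = n), class = "loa_result")
}

#' @export
print.loa_result <- function(x, ...) {
  cat(sprintf("bias %.3f [%.3f, %.3f]; LoA [%.3f, %.3f]  (n = %d)\n",
              x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_low, x$loa_high, x$n))
  invisible(x)
}

rating_matrix_by_key <- function(a, b, keys) {
  ka <- do.call(paste, c(a[keys], sep = "\r"))
  kb <- do.call(paste, c(b[keys], sep = "\r"))
  if (!setequal(unique(ka), unique(kb))) {
    abort(paste0("rater tables disagree on annotated keys: ",
                 paste(head(union(setdiff(ka, kb), setdiff(kb, ka)), 5),
                       collapse = "; ")))
  }
  invisible(NULL)
}

#' Inter-rater reliability report for two annotation cohorts
#'
#' Given the same subjects annotated by two raters, computes per point and
#' axis (x, y, z) the ICC(2,k) across subjects, an axis-level summary
#' (unweighted mean and SD of the per-point ICC estimates), and
#' Bland-Altman limits of agreement. With `aggregate_sides = TRUE`
#' (default) the LoA pools left and right measurements of mirrored points,
#' mirroring how lateral points are usually reported.
#'
#' @param rater1,rater2 Point tibbles covering identical subjects and
#'   point rosters.
#' @param aggregate_sides Pool left/right sides in the LoA table.
#' @param conf_level Confidence level for the ICC intervals.
#' @return A list with tibbles `icc` (per point x axis: clamped estimate
#'   and bounds plus raw estimate), `axis_summary` (mean/SD of ICC per
#'   axis) and `loa` (bias, limits and their Wald CIs per point x axis).
#' @export
reliability_report <- function(rater1, rater2, aggregate_sides = TRUE,
                               conf_level = 0.95) {
  keys <- c("subject_id", "structure", "role", "side", "subpoint")
  for (nm in c(keys, "x_mm", "y_mm", "z_mm")) {
    if (!nm %in% names(rater1) || !nm %in% names(rater2)) {
      abort(paste0("both rater tables need column '", nm, "'"))
    }
  }
  if (!setequal(unique(rater1$subject_id), unique(rater2$subject_id))) {
    abort(paste0("subject mismatch between raters: ",
                 paste(union(setdiff(rater1$subject_id, rater2$subject_id),
                             setdiff(rater2$subject_id, rater1$subject_id)),
                       collapse = ", ")))
  }
  rating_matrix_by_key(rater1, rater2, keys)

  long <- function(tbl, who) {
    tbl |>
      dplyr::select(dplyr::all_of(c(keys, "x_mm", "y_mm", "z_mm"))) |>
      tidyr::pivot_longer(c("x_mm", "y_mm", "z_mm"),
                          names_to = "axis", values_to = who) |>
      dplyr::mutate(axis = sub("_mm$", "", .data$axis))
  }
  paired <- dplyr::inner_join(long(rater1, "r1"), long(rater2, "r2"),
                              by = c(keys, "axis"))

  icc_tab <- paired |>
    dplyr::group_by(.data$structure, .data$role, .data$side,
                    .data$subpoint, .data$axis) |>
    dplyr::group_modify(function(df, key) {
      res <- icc2k(cbind(df$r1, df$r2), conf_level = conf_level)
      tibble::tibble(estimate = res$estimate, ci_low = res$ci_low,
                     ci_high = res$ci_high,
                     estimate_raw = res$raw$estimate, n = res$n)
    }) |>
    dplyr::ungroup()

  axis_summary <- icc_tab |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(mean_icc = mean(.data$estimate),
                     sd_icc = sd(.data$estimate),
                     n_points = dplyr::n(), .groups = "drop")

  loa_groups <- if (aggregate_sides) {
    dplyr::mutate(paired, side = ifelse(.data$side == "midline",
                                        "midline", "lateral"))
  } else paired
  loa_tab <- loa_groups |>
    dplyr::group_by(.data$structure, .data$role, .data$side,
                    .data$subpoint, .data$axis) |>
    dplyr::group_modify(function(df, key) {
      res <- limits_of_agreement(cbind(df$r1, df$r2))
      tibble::tibble(
        bias = res$bias, sd_diff = res$sd_diff,
        loa_low = res$loa_low, loa_high = res$loa_high,
        bias_ci_low = res$ci_bias[1], bias_ci_high = res$ci_bias[2],
        loa_low_ci_low = res$ci_loa_low[1], loa_low_ci_high = res$ci_loa_low[2],
        loa_high_ci_low = res$ci_loa_high[1], loa_high_ci_high = res$ci_loa_high[2],
        n = res$n)
    }) |>
    dplyr::ungroup()

  list(icc = icc_tab, axis_summary = axis_summary, loa = loa_tab)
}
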