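# Cohort-level validation statistics: Spearman correlations, test-time
# truncation curves, and ICC(2,1) interrater reliability.

#' Spearman rank correlation with t-approximation p-value
#'
#' `rs` is the Pearson correlation of average ranks (ties get their average
#' rank); the p-value comes from the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom
#' (two-sided). For `|rs| = 1` the p-value is 0. For `n <= 10` an exact
#' permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param exact compute the exact permutation p-value (only for `n <= 10`).
#' @return list with `rs` and `p`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3L) {
    bd_stop("format_error",
            "spearman_cor needs two equal-length vectors with n >= 3")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    bd_stop("constant_input_error",
            "Spearman correlation undefined for constant input")
  }
  rs <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10L) {
      bd_stop("format_error", "exact permutation p only supported for n <= 10")
    }
    perms <- permutations_of(n)
    rs_null <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rs_null) >= abs(rs) - 1e-12)
  } else if (abs(rs) >= 1) {
    p <- 0
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rs = rs, p = p)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation between a model's fitted values and the ratings
#'
#' The validation statistic for a fitted rating model: the Spearman rank
#' correlation of the model's fitted (predicted) therapist ratings against
#' the observed mean ratings.
#'
#' @param fit a [fit_tqce()] result.
#' @param table the cohort table the model was fitted to (used for the
#'   response column).
#' @return list with `rs` and `p`.
#' @export
predicted_correlation <- function(fit, table = NULL) {
  y <- if (is.null(table)) fit$observed else table[[fit$response]]
  spearman_cor(fit$fitted, y)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation for a complete trials x raters table:
#' `(MS_rows - MS_err) / (MS_rows + (k-1) MS_err + k (MS_cols - MS_err)/n)`,
#' with the mean squares from the two-way ANOVA decomposition (rows =
#' trials/targets, columns = raters).
#'
#' @param ratings numeric matrix or data frame, trials in rows, raters in
#'   columns; `>= 2` rows, `>= 2` columns, no missing values.
#' @return the ICC(2,1) value.
#' @export
icc_2_1 <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) {
    bd_stop("missing_rating_error",
            "ICC(2,1) needs >= 2 trials and >= 2 raters, got %d x %d", n, k)
  }
  if (anyNA(x)) {
    bd_stop("missing_rating_error",
            "ratings table has %d missing value(s)", sum(is.na(x)))
  }
  gm <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_rows - ms_err) /
    (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n)
}

#' Truncate test time and rerun the whole analysis
#'
#' For each truncated test time `T`, frames after `min(fall, T)` are
#' discarded, DT is capped at `T`, the movement and angle indices are
#' recomputed on the truncated frames and (by default) re-standardized
#' within the truncated cohort, both rating models are refitted, and the
#' Spearman correlation of each model's fitted values with the full-length
#' mean therapist ratings is recorded. The ratings are never re-collected:
#' they keep their full-observation values. At `T` equal to the task cap
#' this reproduces the untruncated pipeline exactly.
#'
#' @param recordings list of [trial_recording()] objects.
#' @param tqce full-length mean therapist rating per trial (same order).
#' @param times truncated test times in seconds (default `seq(10, 60, 10)`);
#'   values above the task cap are clipped with a warning.
#' @param config a [birddog_config()].
#' @param restandardize re-standardize SPB/AG within each truncated cohort
#'   (default) instead of reusing the full-length mean and sd.
#' @return a `truncation_curve` data frame: `time_s, r_cv, p_cv, r_dt,
#'   p_dt`, with a `plot()` method.
#' @export
truncate_and_reanalyze <- function(recordings, tqce,
                                   times = seq(10, 60, by = 10),
                                   config = birddog_config(),
                                   restandardize = TRUE) {
  if (length(recordings) != length(tqce)) {
    bd_stop("join_error", "%d recordings but %d ratings",
            length(recordings), length(tqce))
  }
  if (any(times > config$task_cap_s)) {
    warning(sprintf("truncation time(s) above the task cap clipped to %g s",
                    config$task_cap_s))
    times <- pmin(times, config$task_cap_s)
  }
  if (!restandardize) {
    full <- score_cohort(recordings, config)
    mu <- c(spb = mean(log(1 / pmax(full$D_prime, config$d_prime_floor))),
            ag = mean(full$a_raw))
    sg <- c(spb = stats::sd(log(1 / pmax(full$D_prime, config$d_prime_floor))),
            ag = stats::sd(full$a_raw))
  }
  rows <- lapply(times, function(tt) {
    df <- do.call(rbind, lapply(recordings, score_trial, config = config,
                                window_s = tt))
    if (restandardize) {
      df$SPB <- spb_standardize(df$D_prime, config$d_prime_floor)
      df$AG <- ag_standardize(df$a_raw)
    } else {
      df$SPB <- (log(1 / pmax(df$D_prime, config$d_prime_floor)) - mu["spb"]) / sg["spb"]
      df$AG <- (df$a_raw - mu["ag"]) / sg["ag"]
    }
    df$TQCE <- tqce
    fit_cv <- fit_tqce(df, predictors = c("SPB", "AG", "DT_s"))
    fit_dt <- fit_tqce(df, predictors = "DT_s")
    cv <- predicted_correlation(fit_cv, df)
    dt <- predicted_correlation(fit_dt, df)
    data.frame(time_s = tt, r_cv = cv$rs, p_cv = cv$p,
               r_dt = dt$rs, p_dt = dt$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("truncation_curve", "data.frame")
  out
}

#' @export
plot.truncation_curve <- function(x, ...) {
  graphics::plot(x$time_s, x$r_cv, type = "b", pch = 16, col = "steelblue",
                 ylim = range(c(x$r_cv, x$r_dt, 0, 1)),
                 xlab = "test time (s)",
                 ylab = "Spearman r (fitted vs TQCE)", ...)
  graphics::lines(x$time_s, x$r_dt, type = "b", pch = 17, col = "darkorange")
  graphics::legend("bottomright", legend = c("SPB + AG + DT model", "DT-only model"),
                   col = c("steelblue", "darkorange"), pch = c(16, 17), lty = 1,
                   bty = "n")
  invisible(x)
}
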