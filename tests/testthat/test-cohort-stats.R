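test_that("Spearman correlation handles monotone and tied data", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearman_cor(x, x^3 + 2)$rs, 1)
  expect_equal(spearman_cor(x, -sqrt(x))$rs, -1)
  expect_equal(spearman_cor(x, x^3)$p, 0)
  # tied data against an exhaustive rank oracle
  xt <- c(1, 2, 2, 3, 3, 3, 7)
  yt <- c(5, 5, 1, 4, 2, 2, 9)
  expect_equal(spearman_cor(xt, yt)$rs, cor(brute_ranks(xt), brute_ranks(yt)))
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "constant_input_error")
  expect_error(spearman_cor(1:2, 1:2), class = "format_error")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    base <- spearman_cor(x, y)
    warped <- spearman_cor(exp(x / 2), atan(y) + y^3)
    expect_equal(warped$rs, base$rs, tolerance = 1e-12)
    expect_equal(warped$p, base$p, tolerance = 1e-12)
  }
})

test_that("Spearman rs agrees with the standard estimator, p with the t law", {
  set.seed(19)
  x <- rnorm(30)
  y <- x + rnorm(30)
  ours <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rs, unname(ref$estimate), tolerance = 1e-12)
  tval <- ours$rs * sqrt(28 / (1 - ours$rs^2))
  expect_equal(ours$p, 2 * pt(-abs(tval), 28), tolerance = 1e-12)
  # exact permutation p on a tiny sample is close to the approximation
  xe <- c(3, 1, 4, 1, 5)
  ye <- c(9, 2, 6, 5, 3)
  pe <- spearman_cor(xe, ye, exact = TRUE)$p
  expect_gte(pe, 0)
  expect_lte(pe, 1)
  expect_error(spearman_cor(rnorm(11), rnorm(11), exact = TRUE),
               class = "format_error")
})

test_that("standardized single-predictor beta equals the Pearson r", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(10:80, 1)
    d <- data.frame(DT_s = rnorm(n))
    d$TQCE <- 0.6 * d$DT_s + rnorm(n)
    fit <- fit_tqce(d, predictors = "DT_s")
    expect_equal(unname(coef(fit)), cor(d$DT_s, d$TQCE), tolerance = 1e-12)
  }
})

test_that("a response identical to a predictor fits perfectly", {
  d <- data.frame(DT_s = rnorm(20))
  d$TQCE <- d$DT_s
  # lm warns that a perfect fit makes its summary unreliable; expected here
  fit <- suppressWarnings(fit_tqce(d, predictors = "DT_s"))
  expect_equal(unname(coef(fit)), 1, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  expect_equal(predicted_correlation(fit, d)$rs, 1)
})

test_that("nested models: the 3-predictor raw R^2 never loses to DT-only", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(15:60, 1)
    d <- data.frame(SPB = rnorm(n), AG = rnorm(n), DT_s = rnorm(n))
    d$TQCE <- 0.5 * d$DT_s + 0.2 * d$SPB + rnorm(n)
    full <- fit_tqce(d)
    dt <- fit_tqce(d, predictors = "DT_s")
    expect_gte(full$r2, dt$r2)
  }
})

test_that("degenerate fits raise classed errors", {
  d <- data.frame(SPB = rnorm(20))
  d$AG <- d$SPB           # exactly collinear
  d$DT_s <- rnorm(20)
  d$TQCE <- rnorm(20)
  expect_error(fit_tqce(d), class = "collinearity_error")
  d2 <- data.frame(DT_s = rep(1, 10), TQCE = rnorm(10))
  expect_error(fit_tqce(d2, predictors = "DT_s"),
               class = "constant_cohort_error")
  expect_error(fit_tqce(d[1:3, ]), class = "format_error")
})

test_that("fit methods are coherent: predict, residuals, summary", {
  set.seed(31)
  d <- simulate_rating_table(n = 80, seed = 5)
  fit <- fit_tqce(d)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, d), fit$fitted, tolerance = 1e-12)
  expect_equal(residuals(fit), d$TQCE - fit$fitted)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.tqce_fit")
  expect_equal(sm$coefficients$beta, unname(fit$beta))
  expect_output(print(fit), "adjusted R")
  # unstandardized slope relates to the standardized one by the sd ratio
  expect_equal(unname(fit$beta_raw[-1]),
               unname(fit$beta * sd(d$TQCE) / apply(d[1:3], 2, sd)),
               tolerance = 1e-10)
})

test_that("fitted-value correlation of a single-predictor model is the
           predictor's own Spearman correlation", {
  set.seed(37)
  d <- data.frame(DT_s = rnorm(40))
  d$TQCE <- 0.7 * d$DT_s + rnorm(40, 0, 0.5)
  fit <- fit_tqce(d, predictors = "DT_s")
  expect_equal(predicted_correlation(fit, d)$rs,
               spearman_cor(d$DT_s, d$TQCE)$rs, tolerance = 1e-12)
})

test_that("ICC(2,1) matches a from-scratch ANOVA oracle", {
  # perfect agreement
  same <- matrix(rep(c(3, 5, 2, 7, 4), 3), ncol = 3)
  expect_equal(icc_2_1(same), 1)
  # 6 trials x 3 raters against the aov mean-squares decomposition
  set.seed(41)
  x <- matrix(round(runif(18, 1, 7)), 6, 3)
  x <- x + matrix(rep(rnorm(6, 0, 1.5), 3), 6, 3)  # real trial effects
  expect_equal(icc_2_1(x), aov_icc_2_1(x), tolerance = 1e-10)
  # independent noise: reliability near zero
  set.seed(43)
  noise <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(icc_2_1(noise)), 0.1)
  bad <- same
  bad[2, 3] <- NA
  expect_error(icc_2_1(bad), class = "missing_rating_error")
  expect_error(icc_2_1(same[1, , drop = FALSE]),
               class = "missing_rating_error")
})

test_that("truncation at the full cap reproduces the untruncated analysis", {
  set.seed(47)
  co <- generate_cohort(cohort_config(n_participants = 8, fps = 10,
                                      master_seed = 53))
  full <- score_cohort(co$recordings)
  full$TQCE <- co$tqce
  curve <- truncate_and_reanalyze(co$recordings, co$tqce, times = c(20, 60))
  expect_s3_class(curve, "truncation_curve")
  # T = 60 is bit-for-bit the untruncated pipeline
  fit_cv <- fit_tqce(full)
  expect_identical(curve$r_cv[curve$time_s == 60],
                   predicted_correlation(fit_cv, full)$rs)
  fit_dt <- fit_tqce(full, predictors = "DT_s")
  expect_identical(curve$r_dt[curve$time_s == 60],
                   predicted_correlation(fit_dt, full)$rs)
  # truncated DT never exceeds the truncation time
  t20 <- do.call(rbind, lapply(co$recordings, score_trial, window_s = 20))
  expect_true(all(t20$DT_s <= 20))
  expect_true(all(abs(curve$r_cv) <= 1 & abs(curve$r_dt) <= 1))
  expect_warning(
    truncate_and_reanalyze(co$recordings, co$tqce, times = c(30, 70)),
    "clipped")
  # fixed-standardization variant runs and agrees at the full cap
  curve2 <- truncate_and_reanalyze(co$recordings, co$tqce, times = 60,
                                   restandardize = FALSE)
  expect_equal(curve2$r_cv, curve$r_cv[curve$time_s == 60], tolerance = 1e-12)
})
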