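# Standardized-coefficient regression of therapist ratings on the indices.

#' Fit a standardized-coefficient rating model
#'
#' Regresses the mean therapist rating (TQCE) on a subset of the indices.
#' Response and predictors are z-scored (sample sd) before an ordinary
#' least-squares fit, so the reported coefficients are standardized betas:
#' for a single predictor the beta equals the Pearson correlation with the
#' response. Unstandardized coefficients are kept alongside for
#' transparency. Adjusted R-squared uses
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param table cohort data frame holding the response and predictor
#'   columns, one row per trial, no missing values in the analysis columns.
#' @param predictors predictor column names, a subset of the indices
#'   (default `c("SPB", "AG", "DT_s")`).
#' @param response response column name (default `"TQCE"`).
#' @return an object of class `tqce_fit` with components `beta`, `se`
#'   (standardized scale), `beta_raw`, `se_raw` (original scale, incl.
#'   intercept), `r2`, `adj_r2`, `fitted` (response scale), `observed`,
#'   `residuals`, `n`, `predictors`, `response`, and the centering/scaling
#'   constants used. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(SPB = rnorm(50), AG = rnorm(50), DT_s = rnorm(50))
#' d$TQCE <- 0.25 * d$SPB + 0.22 * d$AG + 0.69 * d$DT_s + rnorm(50, 0, 0.5)
#' fit <- fit_tqce(d)
#' coef(fit)
fit_tqce <- function(table, predictors = c("SPB", "AG", "DT_s"),
                     response = "TQCE") {
  miss <- setdiff(c(predictors, response), names(table))
  if (length(miss)) {
    bd_stop("format_error", "cohort table lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  n <- nrow(table)
  p <- length(predictors)
  if (n < p + 2L) {
    bd_stop("format_error", "need at least %d trials to fit %d predictors",
            p + 2L, p)
  }
  X <- as.matrix(table[predictors])
  y <- table[[response]]
  if (anyNA(X) || anyNA(y)) {
    bd_stop("format_error", "missing values in analysis columns")
  }
  x_mu <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd == 0)) {
    bd_stop("constant_cohort_error", "constant predictor(s): %s",
            paste(predictors[x_sd == 0], collapse = ", "))
  }
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd == 0) {
    bd_stop("constant_cohort_error", "response %s is constant", response)
  }
  Z <- sweep(sweep(X, 2, x_mu), 2, x_sd, "/")
  if (p > 1L && kappa(crossprod(Z), exact = TRUE) > 1e8) {
    bd_stop("collinearity_error",
            "predictors are (near-)collinear; standardized betas unstable")
  }
  zy <- (y - y_mu) / y_sd
  dz <- data.frame(zy = zy, Z)
  names(dz) <- c(".zy", predictors)
  fml <- stats::as.formula(paste(".zy ~", paste(sprintf("`%s`", predictors),
                                                collapse = " + ")))
  fit_z <- stats::lm(fml, data = dz)
  sm_z <- summary(fit_z)
  # same model on the original scale, for unstandardized coefficients
  dr <- data.frame(.y = y, X)
  names(dr) <- c(".y", predictors)
  fit_r <- stats::lm(stats::as.formula(paste(".y ~", paste(sprintf("`%s`", predictors),
                                                           collapse = " + "))),
                     data = dr)
  sm_r <- summary(fit_r)
  fitted_y <- y_mu + y_sd * stats::fitted(fit_z)
  structure(
    list(beta = stats::setNames(stats::coef(fit_z)[-1], predictors),
         se = stats::setNames(sm_z$coefficients[-1, "Std. Error"], predictors),
         beta_raw = stats::coef(fit_r),
         se_raw = sm_r$coefficients[, "Std. Error"],
         r2 = sm_z$r.squared,
         adj_r2 = 1 - (1 - sm_z$r.squared) * (n - 1) / (n - p - 1),
         fitted = as.numeric(fitted_y),
         observed = y,
         residuals = as.numeric(y - fitted_y),
         n = n, predictors = predictors, response = response,
         x_center = x_mu, x_scale = x_sd, y_center = y_mu, y_scale = y_sd),
    class = "tqce_fit"
  )
}

#' @export
print.tqce_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<tqce_fit> %s ~ %s  (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  tab <- cbind(beta = x$beta, SE = x$se)
  print(round(tab, digits))
  cat(sprintf("adjusted R^2 = %.*f\n", digits, x$adj_r2))
  invisible(x)
}

#' @export
summary.tqce_fit <- function(object, ...) {
  pc <- predicted_correlation(object)
  out <- list(
    coefficients = data.frame(predictor = object$predictors,
                              beta = unname(object$beta),
                              se = unname(object$se),
                              beta_raw = unname(object$beta_raw[-1]),
                              se_raw = unname(object$se_raw[-1])),
    intercept_raw = unname(object$beta_raw[1]),
    r2 = object$r2, adj_r2 = object$adj_r2,
    predicted_rs = pc$rs, predicted_p = pc$p, n = object$n,
    response = object$response
  )
  class(out) <- "summary.tqce_fit"
  out
}

#' @export
print.summary.tqce_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Standardized regression of %s (n = %d)\n", x$response, x$n))
  print(x$coefficients, digits = digits, row.names = FALSE)
  cat(sprintf("R^2 = %.*f, adjusted R^2 = %.*f\n",
              digits, x$r2, digits, x$adj_r2))
  cat(sprintf("Spearman(fitted, %s): rs = %.*f, p = %.3g\n",
              x$response, digits, x$predicted_rs, x$predicted_p))
  invisible(x)
}

#' @export
coef.tqce_fit <- function(object, standardized = TRUE, ...) {
  if (standardized) object$beta else object$beta_raw
}

#' @export
residuals.tqce_fit <- function(object, ...) object$residuals

#' Predict ratings for new trials
#'
#' New predictors are standardized with the training cohort's centering and
#' scaling constants, then mapped back to the response scale.
#'
#' @param object a `tqce_fit`.
#' @param newdata data frame with the model's predictor columns; omitted,
#'   returns the fitted values.
#' @param ... unused.
#' @return predicted ratings on the response scale.
#' @export
predict.tqce_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- as.matrix(newdata[object$predictors])
  Z <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  object$y_center + object$y_scale * as.numeric(Z %*% object$beta)
}

#' @export
plot.tqce_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$observed,
                 xlab = sprintf("fitted %s", x$response),
                 ylab = sprintf("observed %s", x$response),
                 pch = 16, col = "steelblue", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
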