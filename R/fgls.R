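# Three-stage FGLS estimation of the conditional mean and variance of log
# income, the basis of the expected-poverty vulnerability index:
#   stage 1: OLS of lnY on X            -> beta_OLS, residuals e
#   stage 2: OLS of e^2 on X_v          -> theta_OLS, fitted variances h
#   stage 3: WLS of e^2 on X_v, w=1/h   -> theta_hat (FGLS)
#   stage 4: WLS of lnY on X, w=1/sigma2 with sigma2 = max(X_v theta_hat, eps)
#                                        -> beta_hat (FGLS)
# Fitted variances are floored at eps with per-row flags: regressing squared
# residuals linearly can produce negative fits, a classic failure mode the
# estimator must survive.

#' Income model specification
#'
#' @param mean_covariates ordered covariate names of the mean equation.
#' @param variance_covariates ordered covariate names of the variance
#'   equation; defaults to the mean covariates.
#' @param include_intercept include an intercept in both designs.
#' @return object of class `income_model_spec`.
#' @export
income_model_spec <- function(mean_covariates,
                              variance_covariates = mean_covariates,
                              include_intercept = TRUE) {
  if (anyDuplicated(mean_covariates) || anyDuplicated(variance_covariates)) {
    abort("covariate names must not be duplicated")
  }
  structure(list(mean_covariates = mean_covariates,
                 variance_covariates = variance_covariates,
                 include_intercept = isTRUE(include_intercept)),
            class = "income_model_spec")
}

#' Fit the three-stage FGLS income model
#'
#' @param table household data.frame containing the covariates and the income
#'   column.
#' @param spec an [income_model_spec()].
#' @param income_col name of the income column (strictly positive; rows with
#'   non-positive or missing income are excluded with a message).
#' @param log_income if `TRUE` (default) the response is `log(income)`;
#'   set `FALSE` when `income_col` already holds log income.
#' @param eps variance floor.
#' @param weight_kernel stage-3 weighting kernel applied to the stage-2
#'   fitted variance h: `"floor"` uses 1/max(h, eps) (default), `"abs"` uses
#'   1/max(|h|, eps), `"square"` uses 1/max(h^2, eps).
#' @return object of class `fgls_fit`.
#' @export
fit_income_fgls <- function(table, spec, income_col = "income",
                            log_income = TRUE, eps = 1e-6,
                            weight_kernel = c("floor", "abs", "square")) {
  stopifnot(inherits(spec, "income_model_spec"))
  weight_kernel <- match.arg(weight_kernel)
  if (!income_col %in% names(table)) {
    abort("income column '%s' not found", income_col)
  }
  income <- as.numeric(table[[income_col]])
  keep <- !is.na(income)
  if (log_income) keep <- keep & income > 0
  excluded <- sum(!keep)
  if (excluded > 0) {
    if (log_income && any(income <= 0, na.rm = TRUE)) {
      message(excluded, " row(s) excluded (missing or non-positive income; ",
              "log income requires strictly positive values - supply ",
              "log_income = FALSE if the column is already on the log scale)")
    } else {
      message(excluded, " row(s) excluded (missing income)")
    }
    table <- table[keep, , drop = FALSE]
    income <- income[keep]
  }
  lnY <- if (log_income) log(income) else income

  X <- design_matrix(table, spec$mean_covariates, spec$include_intercept)
  Xv <- design_matrix(table, spec$variance_covariates, spec$include_intercept)
  n <- nrow(X)
  if (n <= max(ncol(X), ncol(Xv))) abort("more coefficients than rows")
  check_full_rank(X, "mean design")
  check_full_rank(Xv, "variance design")

  # stage 1: OLS mean equation
  f1 <- lm.fit(X, lnY)
  beta1 <- f1$coefficients
  e <- as.numeric(f1$residuals)

  # stage 2: OLS of squared residuals
  e2 <- e^2
  f2 <- lm.fit(Xv, e2)
  theta1 <- f2$coefficients
  h <- as.numeric(Xv %*% theta1)

  # stage 3: weighted re-estimation of the variance equation
  w3 <- switch(weight_kernel,
               floor = 1 / pmax(h, eps),
               abs = 1 / pmax(abs(h), eps),
               square = 1 / pmax(h^2, eps))
  f3 <- lm.wfit(Xv, e2, w3)
  theta_hat <- f3$coefficients
  sigma2 <- as.numeric(Xv %*% theta_hat)
  floored <- which(sigma2 < eps)
  sigma2 <- pmax(sigma2, eps)

  # stage 4: weighted mean equation (FGLS)
  f4 <- lm.wfit(X, lnY, 1 / sigma2)
  beta_hat <- f4$coefficients

  structure(list(beta_hat = beta_hat, theta_hat = theta_hat,
                 stage1_beta_ols = beta1, stage1_residuals = e,
                 stage2_theta_ols = theta1, stage2_residuals = f2$residuals,
                 fitted_mean = as.numeric(X %*% beta_hat),
                 fitted_variance = sigma2, n = n,
                 floored_rows = floored, excluded_rows = excluded,
                 eps = eps, weight_kernel = weight_kernel, spec = spec),
            class = "fgls_fit")
}

#' @export
print.fgls_fit <- function(x, ...) {
  cat("Three-stage FGLS income model (n =", x$n, ")\n")
  cat("Mean equation (beta_hat):\n")
  print(round(x$beta_hat, 4))
  cat("Variance equation (theta_hat):\n")
  print(round(x$theta_hat, 4))
  if (length(x$floored_rows) > 0) {
    cat(length(x$floored_rows), "row(s) had fitted variance floored at",
        x$eps, "\n")
  }
  if (x$excluded_rows > 0) cat(x$excluded_rows, "row(s) excluded\n")
  invisible(x)
}

#' Predict expected mean and variance of log income
#'
#' @param fit an [fit_income_fgls()] result.
#' @param newdata data.frame of covariate rows (column order resolved by
#'   name from the fit's specification).
#' @return list with `mu`, `sigma2` (floored at the fit's eps) and
#'   `floored` (indices of floored rows).
#' @export
predict_mean_variance <- function(fit, newdata) {
  stopifnot(inherits(fit, "fgls_fit"))
  X <- design_matrix(newdata, fit$spec$mean_covariates,
                     fit$spec$include_intercept)
  Xv <- design_matrix(newdata, fit$spec$variance_covariates,
                      fit$spec$include_intercept)
  if (ncol(X) != length(fit$beta_hat) || ncol(Xv) != length(fit$theta_hat)) {
    abort("design dimension does not match the fitted model")
  }
  mu <- as.numeric(X %*% fit$beta_hat)
  raw <- as.numeric(Xv %*% fit$theta_hat)
  floored <- which(raw < fit$eps)
  list(mu = mu, sigma2 = pmax(raw, fit$eps), floored = floored)
}

#' Minimum sample size for estimating a prevalence
#'
#' `N = ceiling(u^2 pi (1 - pi) / delta^2)` for anticipated prevalence `pi`,
#' absolute allowable error `delta` and two-tailed critical value `u_alpha`.
#'
#' @param pi anticipated prevalence, in (0, 1).
#' @param delta allowable absolute error, positive.
#' @param alpha two-tailed significance level (used when `u_alpha` is NULL).
#' @param u_alpha standard-normal two-tailed critical value; supply e.g. 1.96
#'   to match tabulated conventions exactly.
#' @return integer minimum sample size.
#' @export
compute_min_sample_size <- function(pi, delta, alpha = 0.05, u_alpha = NULL) {
  if (pi <= 0 || pi >= 1) abort("pi must lie strictly in (0, 1)")
  if (delta <= 0) abort("delta must be positive")
  if (is.null(u_alpha)) {
    if (alpha <= 0 || alpha >= 1) abort("alpha must lie strictly in (0, 1)")
    u_alpha <- qnorm(1 - alpha / 2)
  }
  as.integer(ceiling(u_alpha^2 * pi * (1 - pi) / delta^2))
}
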