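# Quantile regression on the vulnerability index. The check-loss minimiser
# is computed exactly by a vertex-exchange algorithm in compiled code (an
# optimal solution interpolates p observations); standard errors come from a
# paired (row-resampling) bootstrap, which also supplies the cross-quantile
# covariance needed by the Wald tests in one pass.

qr_design <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("X and y dimensions differ")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("non-finite values in the regression inputs")
  }
  check_full_rank(X, "quantile design")
  list(X = X, y = y)
}

boot_indices <- function(n, reps, seed) {
  set.seed(as.integer(seed))
  matrix(sample.int(n, n * reps, replace = TRUE) - 1L, nrow = n, ncol = reps)
}

#' Quantile regression fit
#'
#' Minimizes the check loss `sum(rho_tau(y - X b))` with
#' `rho_tau(u) = u * (tau - 1(u < 0))`.
#'
#' @param X design matrix (include an intercept column if wanted).
#' @param y response vector.
#' @param tau quantile level in (0, 1).
#' @param bootstrap_reps paired-bootstrap replications for standard errors;
#'   0 skips the bootstrap.
#' @param seed bootstrap seed.
#' @return object of class `quantile_fit` with coefficients, bootstrap
#'   standard errors, the attained objective, residuals and solver diagnostics.
#' @export
fit_quantile <- function(X, y, tau, bootstrap_reps = 500, seed = 1L) {
  if (tau <= 0 || tau >= 1) abort("tau must lie strictly in (0, 1)")
  d <- qr_design(X, y)
  core <- .qr_fit_cpp(d$X, d$y, tau)
  coef <- as.numeric(core$coefficients)
  names(coef) <- colnames(d$X)
  se <- rep(NA_real_, length(coef))
  boot <- NULL
  if (bootstrap_reps > 0) {
    idx <- boot_indices(nrow(d$X), bootstrap_reps, seed)
    cube <- .qr_boot_cpp(d$X, d$y, tau, idx)
    boot <- t(cube[, 1, , drop = TRUE])  # reps x p
    if (length(coef) == 1) boot <- matrix(cube[1, 1, ], ncol = 1)
    colnames(boot) <- names(coef)
    ok <- stats::complete.cases(boot)
    if (!all(ok)) {
      warning(sum(!ok), " degenerate bootstrap resample(s) dropped",
              call. = FALSE)
      boot <- boot[ok, , drop = FALSE]
    }
    se <- apply(boot, 2, sd)
  }
  structure(list(coefficients = coef, se = se, tau = tau,
                 objective = core$objective, residuals = d$y - d$X %*% coef,
                 n = nrow(d$X), converged = core$converged,
                 iterations = core$iterations,
                 bootstrap_reps = bootstrap_reps, bootstrap = boot,
                 seed = seed),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression, tau = %.2f (n = %d, objective = %.4f)\n",
              x$tau, x$n, x$objective))
  print(data.frame(estimate = round(x$coefficients, 4),
                   se = round(x$se, 4)))
  invisible(x)
}

#' Ordinary least squares fit with classical standard errors
#'
#' The mean-regression comparison column for the quantile analysis.
#'
#' @param X design matrix.
#' @param y response vector.
#' @return object of class `ols_fit`.
#' @export
fit_ols <- function(X, y) {
  d <- qr_design(X, y)
  f <- lm.fit(d$X, d$y)
  p <- ncol(d$X)
  n <- nrow(d$X)
  sigma2 <- sum(f$residuals^2) / (n - p)
  XtXi <- chol2inv(chol(crossprod(d$X)))
  se <- sqrt(sigma2 * diag(XtXi))
  coef <- f$coefficients
  names(se) <- names(coef)
  tval <- coef / se
  structure(list(coefficients = coef, se = se,
                 t_value = tval,
                 p_value = 2 * stats::pt(-abs(tval), df = n - p),
                 sigma2 = sigma2, df = n - p, residuals = f$residuals,
                 n = n),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit (n =", x$n, ")\n")
  print(data.frame(estimate = round(x$coefficients, 4), se = round(x$se, 4),
                   p = signif(x$p_value, 3)))
  invisible(x)
}

#' Coefficient curves over a grid of quantiles
#'
#' Repeated [fit_quantile()] over `tau_grid`, returned tidy for plotting.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param tau_grid quantile levels; default 0.05 to 0.95 in steps of 0.05.
#' @param bootstrap_reps bootstrap replications per tau (0 = no SEs).
#' @param seed bootstrap seed (one substream per tau).
#' @return data.frame with columns variable, tau, coefficient, se.
#' @export
full_quantile_sweep <- function(X, y, tau_grid = seq(0.05, 0.95, by = 0.05),
                                bootstrap_reps = 0, seed = 1L) {
  out <- lapply(tau_grid, function(tau) {
    f <- fit_quantile(X, y, tau, bootstrap_reps = bootstrap_reps,
                      seed = substream_seed(seed, sprintf("sweep:%.4f", tau)))
    data.frame(variable = names(f$coefficients), tau = tau,
               coefficient = as.numeric(f$coefficients),
               se = as.numeric(f$se), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
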