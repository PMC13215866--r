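# Covariance-based fit indices for the path model, computed from the sample
# and model-implied construct covariance matrices with the standard
# maximum-likelihood discrepancy.

#' Degrees of freedom of a recursive path model
#'
#' Free parameters are one coefficient per edge plus one variance per node;
#' df = p(p+1)/2 minus that count.
#'
#' @param diagram a [path_diagram()].
#' @return integer degrees of freedom.
#' @export
path_model_df <- function(diagram) {
  p <- length(diagram$nodes)
  as.integer(p * (p + 1) / 2 - nrow(diagram$edges) - p)
}

#' Covariance-based fit indices
#'
#' Computes chi-square `(n-1) * (ln|Sigma| + tr(S Sigma^-1) - ln|S| - p)`,
#' the diagonal (independence) baseline chi-square, and GFI, AGFI, PGFI,
#' IFI, CFI, SRMR (root mean square of standardized residuals over the lower
#' triangle including the diagonal) and RMSEA.
#'
#' @param S sample covariance matrix of the constructs.
#' @param Sigma model-implied covariance matrix.
#' @param df_model model degrees of freedom.
#' @param n sample size.
#' @param df_baseline baseline degrees of freedom; default `p(p-1)/2`.
#' @return object of class `fit_index_report`.
#' @export
fit_indices <- function(S, Sigma, df_model, n, df_baseline = NULL) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- ncol(S)
  if (!all(dim(S) == dim(Sigma))) abort("S and Sigma dimensions differ")
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("S and Sigma must be positive definite")
  }
  if (is.null(df_baseline)) df_baseline <- p * (p - 1) / 2

  ml_discrepancy <- function(S, Sig) {
    as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
      sum(diag(S %*% solve(Sig))) -
      as.numeric(determinant(S, logarithm = TRUE)$modulus) - p
  }
  # discrepancies at machine-precision level are numerical zeros (a saturated
  # model must report chi-square exactly 0)
  clamp <- function(x) if (x < p * 1e-8) 0 else x
  chisq <- clamp(max((n - 1) * ml_discrepancy(S, Sigma), 0))
  Sigma_b <- diag(diag(S), p)
  chisq_b <- clamp(max((n - 1) * ml_discrepancy(S, Sigma_b), 0))

  Sinv_ratio <- solve(Sigma) %*% S
  gfi <- 1 - sum(diag((Sinv_ratio - diag(p)) %*% (Sinv_ratio - diag(p)))) /
    sum(diag(Sinv_ratio %*% Sinv_ratio))
  agfi <- if (df_model > 0) {
    1 - (p * (p + 1) / (2 * df_model)) * (1 - gfi)
  } else NA_real_
  pgfi <- (2 * df_model / (p * (p + 1))) * gfi
  ifi <- if (chisq_b - df_model != 0) {
    (chisq_b - chisq) / (chisq_b - df_model)
  } else NA_real_
  cfi_denom <- max(chisq_b - df_baseline, chisq - df_model, 0)
  cfi <- if (cfi_denom > 0) {
    1 - max(chisq - df_model, 0) / cfi_denom
  } else 1
  cfi <- min(max(cfi, 0), 1)

  dmat <- diag(1 / sqrt(diag(S)), p)
  res <- dmat %*% (S - Sigma) %*% dmat
  lower <- res[lower.tri(res, diag = TRUE)]
  srmr <- sqrt(mean(lower^2))
  rmsea <- if (df_model > 0) {
    sqrt(max(chisq - df_model, 0) / (df_model * (n - 1)))
  } else 0

  structure(list(chi_square = chisq, df = df_model,
                 chi_square_baseline = chisq_b, df_baseline = df_baseline,
                 GFI = gfi, AGFI = agfi, PGFI = pgfi, IFI = ifi, CFI = cfi,
                 SRMR = srmr, RMSEA = rmsea, n = n, p = p),
            class = "fit_index_report")
}

#' @export
print.fit_index_report <- function(x, ...) {
  cat(sprintf("chi-square = %.3f (df = %d), baseline = %.3f (df = %d)\n",
              x$chi_square, x$df, x$chi_square_baseline, x$df_baseline))
  cat(sprintf("GFI = %.3f  AGFI = %.3f  PGFI = %.3f\n", x$GFI, x$AGFI,
              x$PGFI))
  cat(sprintf("IFI = %.3f  CFI = %.3f  SRMR = %.3f  RMSEA = %.3f\n",
              x$IFI, x$CFI, x$SRMR, x$RMSEA))
  invisible(x)
}
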