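#' Round half away from zero
#'
#' Survey tables conventionally round 5 upward ("half-up"), unlike base R's
#' round-half-even. Used for all reported percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Derive a reproducible substream seed
#'
#' Expands one master seed into independent per-block seeds keyed by a label,
#' so that adding or disabling one stage never perturbs another's random
#' numbers. Result is a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param label character stream label (e.g. "covariates", "bootstrap").
#' @return integer seed between 0 and 2^31 - 2.
#' @export
substream_seed <- function(master, label) {
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# stop() with call.=FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Build a design matrix (with optional intercept) from named table columns,
# failing loudly on missing columns or non-finite values.
design_matrix <- function(table, covariates, include_intercept = TRUE) {
  missing_cols <- setdiff(covariates, names(table))
  if (length(missing_cols) > 0) {
    abort("columns not found in table: %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(covariates)) {
    abort("duplicated covariate names: %s",
          paste(unique(covariates[duplicated(covariates)]), collapse = ", "))
  }
  X <- if (length(covariates) == 0) {
    matrix(numeric(0), nrow = nrow(table), ncol = 0)
  } else {
    as.matrix(as.data.frame(lapply(table[covariates], as.numeric)))
  }
  if (include_intercept) {
    X <- cbind(`(Intercept)` = rep(1, nrow(table)), X)
  }
  if (!all(is.finite(X))) abort("design matrix contains non-finite values")
  X
}

# Identify (approximately) collinear columns of X by pivoted QR; returns a
# character vector of offending column names (empty if full rank).
collinear_columns <- function(X) {
  qrx <- qr(X)
  if (qrx$rank == ncol(X)) return(character(0))
  dropped <- qrx$pivot[(qrx$rank + 1):ncol(X)]
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(X)))
  cn[dropped]
}

check_full_rank <- function(X, context = "design matrix") {
  bad <- collinear_columns(X)
  if (length(bad) > 0) {
    abort("%s is rank deficient; collinear columns: %s",
          context, paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
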