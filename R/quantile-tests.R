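# Heterogeneity analysis across the vulnerability distribution: collinearity
# screen, cross-quantile Wald tests with V / inverted-V shape labels,
# farming-subgroup equality tests and interaction models.

# Moore-Penrose pseudo-inverse via SVD (used only when a bootstrap covariance
# is numerically singular).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate j on all the others
#' (with intercept). Perfect collinearity yields an infinite VIF and sets the
#' flag rather than raising an error.
#'
#' @param X covariate matrix (no intercept column).
#' @param flag_threshold VIF above which collinearity is flagged; default 10.
#' @return object of class `vif_report`.
#' @export
compute_vif <- function(X, flag_threshold = 10) {
  X <- as.matrix(X)
  if (ncol(X) < 2) abort("VIF needs at least two covariates")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(apply(X, 2, sd) == 0)) {
    abort("constant column in VIF input: %s",
          paste(colnames(X)[apply(X, 2, sd) == 0], collapse = ", "))
  }
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  structure(list(vif = vif, max_vif = max(vif),
                 flag = max(vif) > flag_threshold,
                 flag_threshold = flag_threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  print(round(x$vif, 3))
  cat(sprintf("max VIF = %.3f (collinearity flag: %s)\n", x$max_vif,
              ifelse(x$flag, "YES", "no")))
  invisible(x)
}

#' Classify the cross-quantile coefficient pattern
#'
#' With coefficients at the lower, middle and upper quantile and significance
#' flags for the two adjacent pairwise differences: "Inverted V-shaped" when
#' the middle coefficient is the strict maximum, "V-shaped" when it is the
#' strict minimum, "monotone" when strictly ordered — under the strict rule
#' all three require both pairwise flags; the lenient rule accepts the peak
#' ordering for V / inverted V without significance. Ties give "flat/other".
#'
#' @param c25,c50,c75 coefficients at the three quantiles.
#' @param sig_25_50,sig_50_75 logical pairwise-significance flags.
#' @param rule `"strict"` (default) or `"lenient"`.
#' @return character label.
#' @export
classify_pattern <- function(c25, c50, c75, sig_25_50, sig_50_75,
                             rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  if (!all(is.finite(c(c25, c50, c75)))) abort("non-finite coefficients")
  both <- isTRUE(sig_25_50) && isTRUE(sig_50_75)
  peak <- c50 > max(c25, c75)
  valley <- c50 < min(c25, c75)
  ordered_up <- c25 < c50 && c50 < c75
  ordered_down <- c25 > c50 && c50 > c75
  if (rule == "strict") {
    if (peak && both) return("Inverted V-shaped")
    if (valley && both) return("V-shaped")
    if ((ordered_up || ordered_down) && both) return("monotone")
  } else {
    if (peak) return("Inverted V-shaped")
    if (valley) return("V-shaped")
    if ((ordered_up || ordered_down) && both) return("monotone")
  }
  "flat/other"
}

#' Cross-quantile Wald tests of coefficient equality
#'
#' Fits all quantile levels on each bootstrap resample so the stacked
#' coefficients share one bootstrap covariance; per variable, a joint Wald
#' statistic tests equality across the three levels (df = number of levels
#' minus one) and pairwise tests compare adjacent levels.
#'
#' @param X design matrix (intercept column named "(Intercept)" is reported
#'   but not pattern-classified).
#' @param y response.
#' @param taus quantile levels; default `c(0.25, 0.5, 0.75)`.
#' @param bootstrap_reps bootstrap replications; default 500.
#' @param seed bootstrap seed.
#' @param alpha significance level for the pairwise flags; default 0.05.
#' @param pattern_rule `"strict"` or `"lenient"`, see [classify_pattern()].
#' @param bonferroni apply a Bonferroni correction across variables to the
#'   joint p-values; off by default.
#' @return object of class `cross_quantile_tests`: a data.frame `table` plus
#'   the per-tau fits and the bootstrap draws.
#' @export
cross_quantile_tests <- function(X, y, taus = c(0.25, 0.5, 0.75),
                                 bootstrap_reps = 500, seed = 1L,
                                 alpha = 0.05,
                                 pattern_rule = c("strict", "lenient"),
                                 bonferroni = FALSE) {
  pattern_rule <- match.arg(pattern_rule)
  if (length(taus) != 3) abort("cross-quantile tests expect three taus")
  d <- qr_design(X, y)
  p <- ncol(d$X)
  fits <- lapply(taus, function(tau) .qr_fit_cpp(d$X, d$y, tau))
  coefs <- vapply(fits, function(f) as.numeric(f$coefficients), numeric(p))
  rownames(coefs) <- colnames(d$X) # p x 3

  idx <- boot_indices(nrow(d$X), bootstrap_reps, seed)
  cube <- .qr_boot_cpp(d$X, d$y, taus, idx)   # p x 3 x reps
  complete <- apply(cube, 3, function(m) all(is.finite(m)))
  if (!all(complete)) {
    warning(sum(!complete), " degenerate bootstrap resample(s) dropped",
            call. = FALSE)
    cube <- cube[, , complete, drop = FALSE]
  }

  D <- rbind(c(1, -1, 0), c(0, 1, -1))
  rows <- lapply(seq_len(p), function(j) {
    draws <- t(cube[j, , ])                   # reps x 3
    V <- stats::cov(draws)
    cj <- coefs[j, ]
    DVD <- D %*% V %*% t(D)
    inv <- tryCatch(solve(DVD), error = function(e) NULL)
    if (is.null(inv)) {
      warning("singular bootstrap covariance for '", rownames(coefs)[j],
              "'; using pseudo-inverse", call. = FALSE)
      inv <- pinv(DVD)
    }
    dc <- as.numeric(D %*% cj)
    W <- as.numeric(t(dc) %*% inv %*% dc)
    p_joint <- pchisq(W, df = nrow(D), lower.tail = FALSE)
    se1 <- sqrt(max(V[1, 1] + V[2, 2] - 2 * V[1, 2], 0))
    se2 <- sqrt(max(V[2, 2] + V[3, 3] - 2 * V[2, 3], 0))
    z1 <- if (se1 > 0) dc[1] / se1 else 0
    z2 <- if (se2 > 0) dc[2] / se2 else 0
    p1 <- 2 * pnorm(-abs(z1))
    p2 <- 2 * pnorm(-abs(z2))
    data.frame(variable = rownames(coefs)[j],
               coef_q25 = cj[1], coef_q50 = cj[2], coef_q75 = cj[3],
               wald = W, p_joint = p_joint,
               diff_25_50 = dc[1], se_25_50 = se1, p_25_50 = p1,
               diff_50_75 = dc[2], se_50_75 = se2, p_50_75 = p2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (bonferroni) tab$p_joint <- pmin(tab$p_joint * nrow(tab), 1)
  tab$pattern <- vapply(seq_len(nrow(tab)), function(j) {
    if (tab$variable[j] == "(Intercept)") return("flat/other")
    classify_pattern(tab$coef_q25[j], tab$coef_q50[j], tab$coef_q75[j],
                     tab$p_25_50[j] < alpha, tab$p_50_75[j] < alpha,
                     rule = pattern_rule)
  }, character(1))
  rownames(tab) <- NULL
  structure(list(table = tab, taus = taus, alpha = alpha,
                 pattern_rule = pattern_rule, coefs = coefs,
                 bootstrap_reps = bootstrap_reps, seed = seed,
                 n = nrow(d$X)),
            class = "cross_quantile_tests")
}

#' @export
print.cross_quantile_tests <- function(x, ...) {
  cat(sprintf("Cross-quantile Wald tests at taus %s (n = %d, %d bootstrap reps)\n",
              paste(x$taus, collapse = "/"), x$n, x$bootstrap_reps))
  tab <- x$table
  tab[, sapply(tab, is.numeric)] <- round(tab[, sapply(tab, is.numeric)], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Subgroup regression and between-group coefficient equality tests
#'
#' Fits the full model separately in the two groups defined by a binary
#' column and tests per-variable equality with
#' `(b_A - b_B)^2 / (SE_A^2 + SE_B^2) ~ chi-square(1)`.
#'
#' @param table data.frame with response, covariates and the group column.
#' @param response response column name.
#' @param covariates covariate names.
#' @param group binary (0/1) grouping column name.
#' @param method `"ols"` (default) or `"quantile"`.
#' @param tau quantile level when `method = "quantile"`.
#' @param bootstrap_reps bootstrap replications for quantile SEs.
#' @param seed bootstrap seed.
#' @param min_group_size smallest admissible group.
#' @return object of class `subgroup_comparison`.
#' @export
subgroup_equality <- function(table, response, covariates, group,
                              method = c("ols", "quantile"), tau = 0.5,
                              bootstrap_reps = 200, seed = 1L,
                              min_group_size = 30) {
  method <- match.arg(method)
  g <- table[[group]]
  if (is.null(g)) abort("group column '%s' not found", group)
  vals <- sort(unique(g))
  if (length(vals) != 2) abort("group column must be binary")
  fit_one <- function(sub, label) {
    if (nrow(sub) < min_group_size) {
      abort("group '%s' has fewer than %d rows", label, min_group_size)
    }
    X <- design_matrix(sub, covariates)
    y <- sub[[response]]
    if (method == "ols") {
      f <- fit_ols(X, y)
      list(coef = f$coefficients, se = f$se, n = f$n)
    } else {
      f <- fit_quantile(X, y, tau, bootstrap_reps = bootstrap_reps,
                        seed = substream_seed(seed, paste0("group:", label)))
      list(coef = f$coefficients, se = f$se, n = f$n)
    }
  }
  fa <- fit_one(table[g == vals[1], , drop = FALSE], as.character(vals[1]))
  fb <- fit_one(table[g == vals[2], , drop = FALSE], as.character(vals[2]))
  stat <- (fa$coef - fb$coef)^2 / (fa$se^2 + fb$se^2)
  pval <- pchisq(stat, df = 1, lower.tail = FALSE)
  tab <- data.frame(variable = names(fa$coef),
                    coef_a = as.numeric(fa$coef), se_a = as.numeric(fa$se),
                    coef_b = as.numeric(fb$coef), se_b = as.numeric(fb$se),
                    equality_stat = as.numeric(stat),
                    p_value = as.numeric(pval),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, group = group, group_values = vals,
                 n_a = fa$n, n_b = fb$n, method = method, tau = tau),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf("Subgroup comparison on '%s' (%s = %s: n = %d; %s: n = %d)\n",
              x$group, x$group, x$group_values[1], x$n_a,
              x$group_values[2], x$n_b))
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' OLS with interaction terms appended
#'
#' @param table data.frame.
#' @param response response column name.
#' @param covariates main-effect covariate names.
#' @param interaction_pairs list of character pairs; each adds a product
#'   column named "a:b".
#' @return an `ols_fit` whose coefficients include the interaction terms.
#' @export
fit_interactions <- function(table, response, covariates, interaction_pairs) {
  X <- design_matrix(table, covariates)
  for (pair in interaction_pairs) {
    if (length(pair) != 2) abort("interaction pairs must have two names")
    if (!all(pair %in% names(table))) {
      abort("interaction columns not found: %s",
            paste(setdiff(pair, names(table)), collapse = ", "))
    }
    prod_col <- as.numeric(table[[pair[1]]]) * as.numeric(table[[pair[2]]])
    term <- paste(pair, collapse = ":")
    if (all(prod_col == 0)) {
      abort("interaction term '%s' is identically zero (disjoint indicators)",
            term)
    }
    X <- cbind(X, setNames(data.frame(prod_col), term))
    X <- as.matrix(X)
  }
  bad <- collinear_columns(X)
  if (length(bad) > 0) {
    abort("rank deficiency after appending interactions: %s",
          paste(bad, collapse = ", "))
  }
  fit_ols(X, table[[response]])
}
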