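# Vulnerability index and its summaries. A household's vulnerability is the
# probability that future log income falls below the log poverty line under
# the fitted normal law: v = Phi((ln l - mu) / sqrt(sigma2)). The z-score
# denominator is sqrt of the fitted variance.

#' Expected-poverty vulnerability index
#'
#' @param mu expected log income per household.
#' @param sigma2 fitted variance of log income, strictly positive.
#' @param poverty_line poverty line in currency units (same units as the
#'   income underlying `mu`).
#' @return numeric vector of crossing probabilities in \[0, 1\].
#' @export
vulnerability_index <- function(mu, sigma2, poverty_line) {
  if (poverty_line <= 0) abort("poverty_line must be positive")
  if (any(sigma2 <= 0)) {
    abort("sigma2 must be strictly positive (row %d)", which(sigma2 <= 0)[1])
  }
  if (length(sigma2) == 1) sigma2 <- rep(sigma2, length(mu))
  if (length(mu) != length(sigma2)) abort("mu and sigma2 lengths differ")
  pnorm((log(poverty_line) - mu) / sqrt(sigma2))
}

#' Classify households and summarize the vulnerability distribution
#'
#' Bins are left-closed/right-open except the last, which is closed, so an
#' index of exactly 1 falls in the top bin. The headcount counts households
#' with index greater than or equal to the threshold.
#'
#' @param v vulnerability indices in \[0, 1\].
#' @param threshold classification cutoff in (0, 1); default 0.5.
#' @param bin_edges increasing bin edges spanning the data; default
#'   `c(0, 0.25, 0.5, 0.75, 1)`.
#' @return object of class `vulnerability_distribution` with counts, percents
#'   (2 decimals, half-up), per-bin means and standard deviations, and the
#'   headcount at the threshold.
#' @export
classify_and_summarize <- function(v, threshold = 0.5,
                                   bin_edges = c(0, 0.25, 0.5, 0.75, 1)) {
  if (length(v) == 0) abort("empty vulnerability vector")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("bin_edges must be strictly increasing")
  }
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly in (0, 1)")
  }
  if (any(v < bin_edges[1] | v > bin_edges[length(bin_edges)])) {
    abort("vulnerability values outside the bin range")
  }
  nb <- length(bin_edges) - 1
  idx <- findInterval(v, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = nb)
  n <- length(v)
  bin_means <- vapply(seq_len(nb),
                      function(b) if (counts[b] > 0) mean(v[idx == b]) else NA_real_,
                      numeric(1))
  bin_sds <- vapply(seq_len(nb),
                    function(b) if (counts[b] > 1) sd(v[idx == b]) else NA_real_,
                    numeric(1))
  headcount <- sum(v >= threshold)
  labels <- paste0("[", bin_edges[-length(bin_edges)], ", ",
                   bin_edges[-1],
                   c(rep(")", nb - 1), "]"))
  structure(list(bin_edges = bin_edges, bin_labels = labels, counts = counts,
                 percents = round_half_up(100 * counts / n, 2),
                 bin_means = bin_means, bin_sds = bin_sds,
                 threshold = threshold, headcount_ge_threshold = headcount,
                 headcount_percent = round_half_up(100 * headcount / n, 2),
                 n = n, vulnerable = v >= threshold),
            class = "vulnerability_distribution")
}

#' @export
print.vulnerability_distribution <- function(x, ...) {
  cat("Vulnerability distribution (n =", x$n, ")\n")
  df <- data.frame(bin = x$bin_labels, count = x$counts,
                   percent = x$percents, mean = round(x$bin_means, 3),
                   sd = round(x$bin_sds, 3))
  print(df, row.names = FALSE)
  cat(sprintf("Households with index >= %.2f: %d (%.2f%%)\n",
              x$threshold, x$headcount_ge_threshold, x$headcount_percent))
  invisible(x)
}

#' Relative poverty line as a fraction of per-capita disposable income
#'
#' @param per_capita_disposable_income positive reference income.
#' @param fraction fraction of the reference income, in (0, 1\]; default 0.60.
#' @param rounding rounding mode applied to the resulting line: `"none"`
#'   (default), `"nearest"`, `"floor"` or `"ceiling"` integer currency units.
#' @return poverty line, with the rounding mode recorded as attribute
#'   `"rounding"`.
#' @export
relative_poverty_line <- function(per_capita_disposable_income,
                                  fraction = 0.60,
                                  rounding = c("none", "nearest", "floor",
                                               "ceiling")) {
  rounding <- match.arg(rounding)
  if (per_capita_disposable_income <= 0) {
    abort("per-capita disposable income must be positive")
  }
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  line <- fraction * per_capita_disposable_income
  line <- switch(rounding,
                 none = line,
                 nearest = round_half_up(line, 0),
                 floor = floor(line),
                 ceiling = ceiling(line))
  structure(line, rounding = rounding)
}

#' Tabulate a categorical column with survey-style percentages
#'
#' @param column categorical vector (factor, character or discrete numeric).
#' @param levels optional explicit level order; defaults to factor levels or
#'   sorted unique values.
#' @return data.frame with level, count and percent (2 decimals, half-up).
#' @export
tabulate_levels <- function(column, levels = NULL) {
  if (length(column) == 0) abort("empty column")
  if (is.null(levels)) {
    levels <- if (is.factor(column)) base::levels(column) else
      sort(unique(column[!is.na(column)]))
  }
  counts <- vapply(levels, function(l) sum(column == l, na.rm = TRUE),
                   numeric(1))
  data.frame(level = as.character(levels), count = as.integer(counts),
             percent = round_half_up(100 * counts / length(column), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
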