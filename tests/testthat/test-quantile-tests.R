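test_that("VIF matches closed forms", {
  # exactly orthogonal columns
  X <- cbind(a = rep(c(1, -1), 10), b = rep(c(1, 1, -1, -1), 5))
  v <- compute_vif(X)
  expect_equal(as.numeric(v$vif), c(1, 1))
  expect_false(v$flag)

  # two predictors with sample correlation exactly 0.6
  set.seed(1)
  z1 <- scale(rnorm(200))[, 1]
  z2r <- lm.fit(cbind(1, z1), rnorm(200))$residuals
  z2 <- 0.6 * z1 + sqrt(1 - 0.36) * scale(z2r)[, 1]
  v2 <- compute_vif(cbind(x1 = z1, x2 = z2))
  expect_equal(as.numeric(v2$vif), c(1.5625, 1.5625), tolerance = 1e-8)

  # duplicated column: infinite VIF, flag set, no exception
  v3 <- compute_vif(cbind(x1 = z1, x2 = z1))
  expect_true(all(is.infinite(v3$vif)))
  expect_true(v3$flag)
  expect_error(compute_vif(cbind(z1)), "two covariates")
})

test_that("pattern classification follows the published shape rules", {
  # published V-shape: educational level across the three quantiles
  expect_identical(classify_pattern(-0.0411, -0.1353, -0.0820, TRUE, TRUE),
                   "V-shaped")
  # published inverted V: health status
  expect_identical(classify_pattern(0.0367, 0.0838, 0.0354, TRUE, TRUE),
                   "Inverted V-shaped")
  expect_identical(classify_pattern(1, 2, 3, TRUE, TRUE), "monotone")
  expect_identical(classify_pattern(3, 2, 1, TRUE, TRUE), "monotone")
  # strict rule demands both significance flags
  expect_identical(classify_pattern(0.0367, 0.0838, 0.0354, FALSE, TRUE),
                   "flat/other")
  # lenient rule accepts the peak ordering alone (migrant-worker case)
  expect_identical(classify_pattern(0.0558, 0.0831, 0.0434, FALSE, TRUE,
                                    rule = "lenient"), "Inverted V-shaped")
  # ties break to flat/other
  expect_identical(classify_pattern(1, 1, 0, TRUE, TRUE), "flat/other")
})

test_that("cross-quantile Wald tests detect heteroscedastic slopes", {
  set.seed(21)
  n <- 2000
  x <- runif(n, 0, 2)
  y <- 1 + x + (1 + 0.9 * x) * rnorm(n)   # slope increases with tau
  cq <- cross_quantile_tests(cbind(1, x = x), y, bootstrap_reps = 150,
                             seed = 5)
  row <- cq$table[cq$table$variable == "x", ]
  expect_lt(row$p_joint, 0.05)
  expect_lt(row$coef_q25, row$coef_q50)
  expect_lt(row$coef_q50, row$coef_q75)
})

test_that("noise-free response gives zero differences and zero statistics", {
  set.seed(22)
  X <- cbind(1, rnorm(60))
  y <- as.numeric(X %*% c(2, 1))
  expect_warning(
    cq <- cross_quantile_tests(X, y, bootstrap_reps = 30, seed = 1),
    "singular")
  expect_equal(cq$table$diff_25_50, c(0, 0), tolerance = 1e-10)
  expect_equal(cq$table$diff_50_75, c(0, 0), tolerance = 1e-10)
  expect_equal(cq$table$wald, c(0, 0), tolerance = 1e-10)
})

test_that("subgroup equality: identical groups give zero differences", {
  set.seed(23)
  tab <- data.frame(x = rnorm(200), g = rep(c(0, 1), each = 100))
  tab$y <- 1 + 0.5 * tab$x + rnorm(200)
  tab$x[101:200] <- tab$x[1:100]
  tab$y[101:200] <- tab$y[1:100]
  s <- subgroup_equality(tab, "y", "x", "g", min_group_size = 50)
  expect_equal(s$table$equality_stat, c(0, 0), tolerance = 1e-12)
})

test_that("subgroup equality test has power against differing slopes", {
  # group-specific slopes 0.066 vs 0, mirroring the farming contrast
  reject <- vapply(1:30, function(s) {
    set.seed(300 + s)
    n <- 3000
    tab <- data.frame(x = rpois(2 * n, 0.6), g = rep(c(1, 0), each = n))
    tab$y <- 0.3 + 0.066 * tab$x * tab$g + rnorm(2 * n, sd = 0.5)
    out <- subgroup_equality(tab, "y", "x", "g")
    out$table$p_value[out$table$variable == "x"] < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.8)
})

test_that("subgroup equality test holds its size under equal slopes", {
  reject <- vapply(1:300, function(s) {
    set.seed(5000 + s)
    n <- 400
    tab <- data.frame(x = rnorm(2 * n), g = rep(c(1, 0), each = n))
    tab$y <- 0.3 + 0.1 * tab$x + rnorm(2 * n)
    out <- subgroup_equality(tab, "y", "x", "g")
    out$table$p_value[out$table$variable == "x"] < 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(mean(reject) - 0.05), 3 * mc_se)
})

test_that("interaction models recover generative interactions", {
  set.seed(25)
  n <- 4000
  tab <- data.frame(x = rnorm(n), g = rbinom(n, 1, 0.5))
  # no interaction in the generative model
  tab$y <- 0.2 + 0.4 * tab$x - 0.1 * tab$g + rnorm(n)
  f0 <- fit_interactions(tab, "y", c("x", "g"), list(c("x", "g")))
  expect_lt(abs(f0$coefficients[["x:g"]]), 3 * f0$se[["x:g"]])
  # +0.05 interaction
  tab$y2 <- 0.2 + 0.4 * tab$x - 0.1 * tab$g + 0.05 * tab$x * tab$g + rnorm(n)
  f1 <- fit_interactions(tab, "y2", c("x", "g"), list(c("x", "g")))
  expect_lt(abs(f1$coefficients[["x:g"]] - 0.05), 3 * f1$se[["x:g"]])
  # disjoint binary indicators produce an all-zero product column
  tab$a <- as.numeric(seq_len(n) <= n / 2)
  tab$b <- 1 - tab$a
  expect_error(fit_interactions(tab, "y", c("a", "b"), list(c("a", "b"))),
               "identically zero")
})
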