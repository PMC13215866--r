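test_that("covariate generation is seed-deterministic and marginally calibrated", {
  cfg <- synthetic_config(n_households = 100, seed = 7)
  expect_identical(generate_covariates(cfg), generate_covariates(cfg))

  cfg_big <- synthetic_config(n_households = 10000, seed = 11)
  covs <- generate_covariates(cfg_big)
  expect_equal(nrow(covs), 10000)
  targets <- c(health_status = 0.6927, building_material = 0.0075,
               tap_water = 0.9549, latrines_type = 0.0885,
               sep_housing_kitchen = 0.7497, medical_insurance = 0.95,
               medical_debt = 0.15)
  for (v in names(targets)) {
    p <- targets[[v]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(covs[[v]]) - p), 3 * se)
    expect_true(all(covs[[v]] %in% c(0, 1)))
  }
  counts <- c("labor_force", "migrant_workers", "agri_machines",
              "durable_products", "household_size")
  for (v in counts) {
    expect_true(all(covs[[v]] >= 0 & covs[[v]] == floor(covs[[v]])))
  }
  expect_true(all(is.finite(covs$cultivated_area)))
})

test_that("degenerate bernoulli marginal yields a zero column", {
  spec <- default_covariate_spec()
  idx <- which(vapply(spec, `[[`, character(1), "name") == "latrines_type")
  spec[[idx]]$params$p <- 0
  cfg <- synthetic_config(n_households = 200, seed = 3, covariate_spec = spec)
  covs <- generate_covariates(cfg)
  expect_true(all(covs$latrines_type == 0))
})

test_that("infeasible variance specifications are rejected", {
  cfg <- synthetic_config(n_households = 50, seed = 5,
                          theta_true = c(-1, 0, 0, 0), max_resample = 3L)
  expect_error(generate_covariates(cfg), "infeasible variance specification")
})

test_that("generate_income draws from the configured conditional law", {
  set.seed(1)
  n <- 10000
  X <- cbind(1, runif(n, 0.5, 1.5))
  beta <- c(9, 0.3)
  # homoscedastic: variance loads only on the intercept
  lnY <- generate_income(X, beta, c(0.25, 0), seed = 2)
  expect_lt(abs(var(lnY - X %*% beta) - 0.25), 0.025)
  expect_identical(lnY, generate_income(X, beta, c(0.25, 0), seed = 2))

  # epsilon-variance: output collapses onto the conditional mean
  eps <- 1e-8
  lnY0 <- generate_income(X, beta, c(eps, 0), seed = 3)
  expect_lt(max(abs(lnY0 - X %*% beta)), 5 * sqrt(eps))

  expect_error(generate_income(X, beta, c(0.1, -0.5), seed = 1),
               "non-positive row variance")
})

test_that("ground-truth vulnerability matches the income law", {
  cfg <- synthetic_config(n_households = 20000, seed = 21)
  sv <- generate_survey(cfg)
  expect_equal(nrow(sv$table), 20000)
  expect_true(all(sv$true_vulnerability > 0 & sv$true_vulnerability < 1))
  # the mean crossing probability is the expected poverty headcount
  headcount <- mean(sv$table$income < cfg$poverty_line)
  v <- sv$true_vulnerability
  mc_se <- sqrt(mean(v * (1 - v)) / length(v))
  expect_lt(abs(headcount - mean(v)), 2 * mc_se)

  # a poverty line far below attainable incomes gives negligible vulnerability
  cfg_low <- synthetic_config(n_households = 500, seed = 22, poverty_line = 20)
  sv_low <- generate_survey(cfg_low)
  expect_true(all(sv_low$true_vulnerability < 0.01))
})

test_that("severing the human -> utilization link removes the association", {
  sp <- default_structural_paths()
  sp$human_utilization <- 0
  cfg <- synthetic_config(n_households = 10000, seed = 31,
                          structural_paths = sp)
  sv <- generate_survey(cfg)
  r <- cor(sv$latents[, "human"], sv$latents[, "utilization"])
  expect_lt(abs(r), 3 / sqrt(10000))
})

test_that("survey regeneration with the same seed is identical", {
  cfg <- small_config(n = 300, seed = 17)
  s1 <- generate_survey(cfg)
  s2 <- generate_survey(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$true_vulnerability, s2$true_vulnerability)
})

test_that("config validation catches inconsistent specifications", {
  expect_error(synthetic_config(beta_true = c(1, 2)), "beta_true")
  expect_error(synthetic_config(theta_true = c(1, 2)), "theta_true")
  expect_error(synthetic_config(farming_share = 1.2), "farming_share")
  expect_error(synthetic_config(mean_covariates = c("nope"),
                                beta_true = c(1, 2)),
               "mean_covariates")
})
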