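test_that("composites are sign-aligned standardized scores", {
  set.seed(1)
  tab <- data.frame(a = rnorm(50, 5, 2), b = rnorm(50), c = runif(50))
  # single-indicator construct equals the z-score
  spec1 <- construct_spec(list(k = c(a = 1)))
  comp <- build_composites(tab, spec1)
  expect_equal(comp$k, as.numeric(scale(tab$a)), tolerance = 1e-12)
  # two perfectly correlated indicators collapse onto the shared z-score
  tab$b2 <- 2 * tab$a + 3
  comp2 <- build_composites(tab, construct_spec(list(k = c(a = 1, b2 = 1))))
  expect_equal(comp2$k, as.numeric(scale(tab$a)), tolerance = 1e-10)
  # a -1 sign flips the indicator's correlation with its composite
  toy <- data.frame(p = c(1, 2, 4), q = c(2, 1, 7))
  cpos <- build_composites(toy, construct_spec(list(k = c(p = 1, q = 1))))
  cneg <- build_composites(toy, construct_spec(list(k = c(p = -1, q = 1))))
  expect_gt(cor(toy$p, cpos$k), 0)
  expect_lt(cor(toy$p, cneg$k), cor(toy$p, cpos$k))
  # constant indicators are rejected by name
  tab$const <- 1
  expect_error(build_composites(tab, construct_spec(list(k = c(const = 1)))),
               "const")
})

test_that("construct and diagram validation", {
  expect_error(construct_spec(list(a = c(x = 1), b = c(x = 1))),
               "more than one construct")
  expect_error(construct_spec(list(a = c(x = 2))), "\\+1 or -1")
  expect_error(path_diagram(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cycle")
  d <- default_path_diagram()
  expect_true(all(c("human", "physical", "social", "utilization",
                    "vulnerability") %in% d$nodes))
  # topological order: every edge goes forward
  pos <- match(d$edges$from, d$nodes) < match(d$edges$to, d$nodes)
  expect_true(all(pos))
})

test_that("single-edge model on standardized data returns the correlation", {
  set.seed(2)
  n <- 500
  a <- rnorm(n)
  b <- 0.6 * a + rnorm(n)
  comp <- data.frame(a = as.numeric(scale(a)), b = as.numeric(scale(b)))
  fit <- fit_path_model(comp, path_diagram(data.frame(from = "a", to = "b")),
                        bootstrap_reps = 0)
  expect_equal(fit$edges$estimate, cor(a, b), tolerance = 1e-10)
})

test_that("structural coefficients of the construct DAG are recovered", {
  set.seed(3)
  n <- 10000
  sp <- published_path_coefficients()
  human <- rnorm(n)
  physical <- 0.733 * human + sqrt(1 - 0.733^2) * rnorm(n)
  social <- 0.456 * physical + sqrt(1 - 0.456^2) * rnorm(n)
  utilization <- -0.128 * human + sqrt(1 - 0.128^2) * rnorm(n)
  lin <- 0.415 * human - 0.433 * physical - 0.195 * social -
    0.035 * utilization
  vulnerability <- lin + sqrt(max(1 - var(lin), 0.1)) * rnorm(n)
  comp <- as.data.frame(lapply(
    list(human = human, physical = physical, social = social,
         utilization = utilization, vulnerability = vulnerability),
    function(x) as.numeric(scale(x))))
  fit <- fit_path_model(comp, default_path_diagram(), bootstrap_reps = 100,
                        seed = 4)
  merged <- merge(fit$edges, sp, by = c("from", "to"),
                  suffixes = c("", "_true"))
  expect_true(all(abs(merged$estimate - merged$estimate_true) <
                    pmax(3 * merged$se, 0.05)))
  # permuting household order leaves estimates unchanged
  fit2 <- fit_path_model(comp[sample.int(n), ], default_path_diagram(),
                         bootstrap_reps = 0)
  expect_equal(fit2$edges$estimate, fit$edges$estimate, tolerance = 1e-10)
})

test_that("effect decomposition matches hand enumeration on a chain", {
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"),
                      estimate = c(0.5, 0.4))
  eff <- decompose_effects(edges)
  ac <- eff[eff$from == "a" & eff$to == "c", ]
  expect_equal(ac$direct, 0)
  expect_equal(ac$indirect, 0.2)
  expect_equal(ac$total, 0.2)
})

test_that("matrix decomposition equals path enumeration on random DAGs", {
  set.seed(6)
  for (k in 1:200) {
    dag <- random_dag(sample(3:8, 1))
    eff <- decompose_effects(dag)
    for (i in sample(nrow(eff), min(3, nrow(eff)))) {
      total_oracle <- enumerate_path_effects(dag, eff$from[i], eff$to[i])
      indirect_oracle <- enumerate_path_effects(dag, eff$from[i], eff$to[i],
                                                min_edges = 2)
      expect_equal(eff$total[i], total_oracle, tolerance = 1e-10)
      expect_equal(eff$indirect[i], indirect_oracle, tolerance = 1e-10)
    }
    # additivity holds exactly for every pair
    expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-12)
  }
})

test_that("implied covariance matches closed forms and simulation", {
  # empty edge set: Sigma = Psi
  d0 <- path_diagram(data.frame(from = "a", to = "b"))
  fit0 <- list(edges = data.frame(from = "a", to = "b", estimate = 0),
               psi = c(a = 1, b = 1))
  Sig0 <- implied_covariance(fit0$edges, d0, psi = fit0$psi)
  expect_equal(unname(Sig0), diag(2))
  # single edge with coefficient r: cov = r, var(b) = r^2 + psi_b
  r <- 0.7
  Sig1 <- implied_covariance(
    data.frame(from = "a", to = "b", estimate = r), d0,
    psi = c(a = 1, b = 1 - r^2))
  expect_equal(Sig1["a", "b"], r)
  expect_equal(Sig1["b", "b"], 1)
  # full construct DAG against a Monte-Carlo covariance
  set.seed(7)
  n <- 200000
  human <- rnorm(n)
  physical <- 0.7 * human + sqrt(1 - 0.49) * rnorm(n)
  social <- 0.5 * physical + sqrt(0.75) * rnorm(n)
  edges <- data.frame(from = c("human", "physical"),
                      to = c("physical", "social"),
                      estimate = c(0.7, 0.5))
  Sig <- implied_covariance(edges, path_diagram(edges[c("from", "to")]),
                            psi = c(human = 1, physical = 0.51,
                                    social = 0.75))
  S_mc <- cov(cbind(human = human, physical = physical, social = social))
  expect_lt(max(abs(Sig - S_mc[rownames(Sig), colnames(Sig)])), 0.01)
})

test_that("significance stars follow the two-level convention", {
  tab <- data.frame(p_value = c(0.03, 0.0005, 0.20))
  expect_identical(significance_report(tab)$stars, c("*", "**", ""))
})
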