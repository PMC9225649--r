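test_that("moment matching reproduces the worked algebra", {
  g <- gamma_moments(100, 10)
  expect_equal(g$shape, 100)
  expect_equal(g$scale, 1)
  b <- beta_moments(0.5, 0.1)
  expect_equal(b$alpha, 12)
  expect_equal(b$beta, 12)
  expect_error(beta_moments(0.5, 0.6), "infeasible beta moments")
  expect_error(gamma_moments(0, 1), "positive")

  set.seed(1)
  expect_equal(sample_parameter(list(family = "gamma", mean = 5, se = 0), 4),
               rep(5, 4))
  set.seed(1)
  u <- sample_parameter(list(family = "normal", mean = 0.9, se = 0.2), 500)
  expect_true(all(u >= 0 & u <= 1))
  set.seed(1)
  p <- sample_parameter(list(family = "beta", mean = 0.3, se = 0.05), 500)
  expect_true(all(p > 0 & p < 1))
  expect_error(sample_parameter(list(family = "weibull", mean = 1, se = 1)),
               "unknown distribution family")
})

test_that("one-way analysis varies one parameter at a time and restores base", {
  cfg <- base_config()
  params <- data.frame(
    path = c("sustained_response.annual_p_sustain",
             "drug_cost.price_per_administration",
             "demographics.male_fraction",
             "markov_state_costs.controlled"),
    base = c(0.98, 580, 0.604, 8937),
    low = c(0.98 * 0.9, 580, 0.604 * 0.9, 8937),
    high = c(0.98, 2 * 580, 0.604 * 1.1, 8937),
    stringsAsFactors = FALSE)
  tor <- owsa(cfg, params)
  expect_s3_class(tor, "owsa_result")
  expect_true(all(tor$span >= 0))
  expect_true(all(diff(tor$span) <= 0))  # sorted descending

  # degenerate bounds give zero span; unused parameters give zero span
  sus <- tor[tor$path == "drug_cost.price_per_administration", ]
  expect_gt(sus$icur_high, sus$icur_low)  # a dupilumab-only cost raises the ICUR
  mf <- tor[tor$path == "demographics.male_fraction", ]
  expect_equal(mf$span, 0)  # male fraction plays no computational role
  deg <- tor[tor$path == "markov_state_costs.controlled", ]
  expect_equal(deg$span, 0)
  expect_equal(deg$icur_low, deg$icur_high)

  # the input configuration is untouched and run order cannot matter
  expect_equal(cfg$drug_cost$price_per_administration, 580)
  tor_rev <- owsa(cfg, params[rev(seq_len(nrow(params))), ])
  expect_equal(tor[order(tor$path), ]$icur_low,
               tor_rev[order(tor_rev$path), ]$icur_low)

  expect_error(owsa(cfg, data.frame(path = "no.such.param", low = 1, high = 2)),
               "not found")
})

test_that("the PSA is seed-reproducible and collapses to the base case at zero SE", {
  cfg <- base_config()
  p1 <- psa(cfg, n = 25, seed = 7)
  p2 <- psa(cfg, n = 25, seed = 7)
  expect_identical(p1$delta_cost, p2$delta_cost)
  expect_identical(p1$draws, p2$draws)
  p3 <- psa(cfg, n = 25, seed = 8)
  expect_false(identical(p1$delta_cost, p3$delta_cost))

  specs0 <- psa_distribution_specs(cfg)
  specs0$se <- 0
  p0 <- psa(cfg, n = 5, seed = 1, specs = specs0)
  base <- icur(run_arm(cfg, "dupilumab"), run_arm(cfg, "bsc"))
  expect_equal(p0$delta_cost, rep(base$delta_cost, 5))
  expect_equal(p0$delta_qaly, rep(base$delta_qaly, 5))

  bad <- specs0
  bad$se[bad$family == "beta"][1] <- 0.9  # infeasible moments
  expect_error(psa(cfg, n = 2, seed = 1, specs = bad), "infeasible")
})

test_that("the acceptability curve is a probability with the right endpoints", {
  cfg <- base_config()
  ps <- psa(cfg, n = 40, seed = 3)
  grid <- c(0, 1e4, 32500, 1e5, 1e9)
  curve <- ceac(ps, grid)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_equal(curve$probability[1], mean(ps$delta_cost <= 0))
  expect_equal(curve$probability[nrow(curve)],
               mean(ps$delta_qaly > 0 |
                      (ps$delta_qaly == 0 & ps$delta_cost <= 0)))
  if (all(ps$delta_qaly >= 0))
    expect_true(all(diff(curve$probability) >= 0))
  expect_error(ceac(ps, numeric(0)), "non-empty")
})

test_that("scenario constructors flip exactly one lever", {
  cfg <- base_config()
  soc <- scenario_societal(cfg)
  expect_equal(soc$econ$perspective, "societal")
  soc$econ$perspective <- cfg$econ$perspective
  expect_equal(unclass(soc), unclass(cfg))
  no_ind <- cfg; no_ind$indirect$workdays_lost_per_year_by_state <- NULL
  expect_error(scenario_societal(no_ind), "workdays")

  cmp <- scenario_compliance(cfg, 0.9695)
  expect_equal(cmp$drug_cost$compliance, 0.9695)
  expect_error(scenario_compliance(cfg, 0), "compliance rate")
  expect_error(scenario_compliance(cfg, 1.2), "compliance rate")

  fit <- cua(cfg)
  fit_cmp1 <- cua(scenario_compliance(cfg, 1.0))
  expect_equal(fit_cmp1$cea$delta_cost, fit$cea$delta_cost)
  fit_cmp <- cua(cmp)
  expect_equal(fit_cmp$arms$dupilumab$qalys, fit$arms$dupilumab$qalys)
})
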