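# A one-cycle trace built by hand, for unit-valuation checks.
fake_trace <- function(state, surgery_entries = 0) {
  occ <- matrix(0, 1, 7, dimnames = list(NULL, health_states()))
  occ[1, state] <- 1
  structure(list(cycle = 1L, age = 52.39, occupancy = occ,
                 surgery_entries = surgery_entries,
                 alive = 1 - occ[1, "DEATH"],
                 entry = occ[1, ]), class = "cohort_trace")
}

# A tree outcome with every year-1 cost and QALY zeroed out.
null_tree <- function() {
  structure(list(arm = "bsc", qaly = 0,
                 costs = list(therapy = 0, medical = 0, drug_acquisition = 0,
                              adverse_events = 0),
                 entry = NULL), class = "tree_outcome")
}

test_that("discount factors follow (1 + r)^-t", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0.03, 10), 1.03^-10)
  expect_equal(discount_factor(0, 7), 1.0)
})

test_that("discounted QALYs match geometric closed forms", {
  # full health, no discounting, 10 cycles: one tree year plus ten
  cfg <- finite_horizon_config(cycles = 10)
  cfg$econ$discount_rate_effects <- 0
  cfg$tree_utilities <- lapply(cfg$tree_utilities, function(x) 1)
  cfg$markov_utilities[c("u_controlled", "u_inadequate", "u_surgery",
                         "u_postop_controlled", "u_postop_uncontrolled")] <-
    list(1, 1, 1, 1, 1)
  cfg$response[c("p_resp_wk24_bsc", "p_resp_wk52_given_wk24_bsc")] <- list(1, 1)
  lt0 <- zero_mortality_lt()
  tree <- run_tree(cfg, "bsc")
  tr <- run_markov(tree$entry, cfg, lt0)
  expect_equal(lifetime_qalys(tree, tr, cfg$markov_utilities, cfg$econ), 11)
  expect_equal(lifetime_life_years(tr, cfg$econ), 11)

  # sustained control forever, 3% discounting: year 1 + u * annuity factor
  cfg2 <- finite_horizon_config(cycles = 25)
  cfg2$sustained_response$annual_p_sustain <- 1.0
  cfg2$response[c("p_resp_wk24_dup", "p_resp_wk52_given_wk24_dup")] <- list(1, 1)
  tree2 <- run_tree(cfg2, "dupilumab")
  tr2 <- run_markov(tree2$entry, cfg2, lt0)
  expect_equal(
    lifetime_qalys(tree2, tr2, cfg2$markov_utilities, cfg2$econ),
    tree2$qaly + 0.913 * sum(1.03^-(1:25)))

  # raising the discount rate never raises QALYs
  econ_hi <- cfg2$econ; econ_hi$discount_rate_effects <- 0.06
  expect_lt(lifetime_qalys(tree2, tr2, cfg2$markov_utilities, econ_hi),
            lifetime_qalys(tree2, tr2, cfg2$markov_utilities, cfg2$econ))
})

test_that("state and surgery costs accrue on occupancy and entry flows", {
  cfg <- base_config()
  cfg$econ$discount_rate_costs <- 0

  # a full cohort passing through Surgery costs one episode (CT + procedure)
  cb <- lifetime_costs(null_tree(), fake_trace("SURGERY", surgery_entries = 1),
                       cfg, "bsc")
  expect_equal(cb$disease_management, 104 + 2009)

  # a post-operative controlled year costs the state cost plus follow-up
  cb2 <- lifetime_costs(null_tree(), fake_trace("POSTOP_CONTROLLED"), cfg, "bsc")
  expect_equal(cb2$disease_management, 8937 + 103)

  # follow-up can be folded into the state cost via its switch
  cfg_nf <- cfg; cfg_nf$switches$followup_on_postop_states <- FALSE
  cb3 <- lifetime_costs(null_tree(), fake_trace("POSTOP_CONTROLLED"), cfg_nf, "bsc")
  expect_equal(cb3$disease_management, 8937)

  # dupilumab acquisition accrues only on Controlled-disease occupancy
  cb4 <- lifetime_costs(null_tree(), fake_trace("CONTROLLED"), cfg, "dupilumab")
  expect_equal(cb4$drug_acquisition, 580 * 26)
  cb5 <- lifetime_costs(null_tree(), fake_trace("INADEQ_ELIG"), cfg, "dupilumab")
  expect_equal(cb5$drug_acquisition, 0)
  expect_equal(cb5$disease_management, 16536)
})

test_that("the cost breakdown is consistent, linear, and perspective-aware", {
  cfg <- base_config()
  fit <- cua(cfg)
  for (arm in c("dupilumab", "bsc")) {
    cb <- fit$arms[[arm]]$costs
    expect_equal(cb$total,
                 cb$drug_acquisition + cb$disease_management +
                   cb$adverse_events + cb$indirect,
                 tolerance = 1e-9)
    expect_equal(cb$indirect, 0)  # NHS perspective
  }

  # zeroing every unit cost zeroes the total
  c0 <- cfg
  c0$tree_costs <- lapply(cfg$tree_costs, function(g) lapply(g, function(x) 0))
  c0$markov_state_costs <- lapply(cfg$markov_state_costs, function(x) 0)
  c0$drug_cost$price_per_administration <- 0
  c0$adverse_events$unit_cost <- 0
  c0$surgery_costs[c("ct_scan", "procedure", "annual_followup")] <- list(0, 0, 0)
  c0$surgery_costs$visit_tariff <- 0
  fit0 <- cua(c0)
  expect_equal(fit0$arms$dupilumab$costs$total, 0)
  expect_equal(fit0$arms$bsc$costs$total, 0)
  # and QALYs are untouched by costs
  expect_equal(fit0$arms$dupilumab$qalys, fit$arms$dupilumab$qalys)

  # compliance scales drug acquisition exactly and nothing else
  c_cmp <- scenario_compliance(cfg, 0.5)
  fit_cmp <- cua(c_cmp)
  expect_equal(fit_cmp$arms$dupilumab$costs$drug_acquisition,
               0.5 * fit$arms$dupilumab$costs$drug_acquisition)
  expect_equal(fit_cmp$arms$dupilumab$costs$disease_management,
               fit$arms$dupilumab$costs$disease_management)

  # discounting strictly reduces lifetime costs
  c_nd <- cfg
  c_nd$econ$discount_rate_costs <- 0
  expect_gt(cua(c_nd)$arms$bsc$costs$total, fit$arms$bsc$costs$total)

  # societal perspective requires the indirect specification
  c_soc <- scenario_societal(cfg)
  c_soc$indirect$workdays_lost_per_year_by_state <- NULL
  arm <- fit$arms$bsc
  expect_error(lifetime_costs(arm$tree, arm$trace, c_soc, "bsc"),
               "indirect-cost specification")
})

test_that("the half-cycle correction averages adjacent occupancies", {
  cfg <- finite_horizon_config(cycles = 10)
  cfg$econ$discount_rate_effects <- 0
  cfg$response[c("p_resp_wk24_bsc", "p_resp_wk52_given_wk24_bsc")] <- list(1, 1)
  lt0 <- zero_mortality_lt()
  tree <- run_tree(cfg, "bsc")
  tr <- run_markov(tree$entry, cfg, lt0)
  plain <- lifetime_qalys(tree, tr, cfg$markov_utilities, cfg$econ)
  econ_h <- cfg$econ; econ_h$half_cycle_correction <- TRUE
  half <- lifetime_qalys(tree, tr, cfg$markov_utilities, econ_h)
  # occupancy decays from Controlled (u = .913) toward lower-utility states,
  # so averaging with the richer start of each cycle raises the total
  expect_gt(half, plain)
  # closed form for the first cycle's correction
  u <- cfg$markov_utilities
  uvec <- c(u$u_controlled, u$u_inadequate, u$u_inadequate, u$u_surgery,
            u$u_postop_controlled, u$u_postop_uncontrolled, 0)
  expected_first <- (sum(tr$entry * uvec) + sum(tr$occupancy[1, ] * uvec)) / 2
  direct_first <- sum(tr$occupancy[1, ] * uvec)
  expect_equal(half - plain,
               sum(vapply(seq_len(10), function(k) {
                 prev <- if (k == 1) tr$entry else tr$occupancy[k - 1, ]
                 sum((prev - tr$occupancy[k, ]) * uvec) / 2
               }, numeric(1))))
  expect_equal(expected_first - direct_first,
               sum((tr$entry - tr$occupancy[1, ]) * uvec) / 2)
})
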