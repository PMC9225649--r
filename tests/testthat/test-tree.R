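test_that("branch probabilities partition the cohort per arm", {
  resp <- list(p_resp_wk24_dup = 0.6, p_resp_wk52_given_wk24_dup = 0.8,
               p_resp_wk24_bsc = 0, p_resp_wk52_given_wk24_bsc = 0.5)
  expect_equal(branch_probabilities(resp, "dupilumab"),
               c(NR24 = 0.4, NR52 = 0.12, R52 = 0.48))
  expect_equal(branch_probabilities(resp, "bsc"),
               c(NR24 = 1, NR52 = 0, R52 = 0))
  resp$p_resp_wk24_dup <- 1; resp$p_resp_wk52_given_wk24_dup <- 1
  expect_equal(branch_probabilities(resp, "dupilumab"),
               c(NR24 = 0, NR52 = 0, R52 = 1))
  expect_error(branch_probabilities(resp, "nope"), "unknown arm")

  set.seed(4)
  for (i in 1:25) {
    r <- list(p_resp_wk24_dup = runif(1), p_resp_wk52_given_wk24_dup = runif(1))
    expect_equal(sum(branch_probabilities(r, "dupilumab")), 1)
  }

  expect_equal(conditional_from_marginal(0.48, 0.6), 0.8)
  expect_error(conditional_from_marginal(0.7, 0.6), "cannot exceed")
})

test_that("year-1 QALYs time-weight the tree utilities over 52 weeks", {
  u <- base_config()$tree_utilities
  expect_equal(year1_qaly("R52", u, "dupilumab"),
               (12 * 0.769 + 12 * 0.875 + 28 * 0.891) / 52)
  expect_equal(year1_qaly("NR24", u, "bsc"),
               (12 * 0.769 + 12 * 0.810 + 28 * 0.808) / 52)
  # week-52 failures keep responder utility until the week-52 assessment
  expect_equal(year1_qaly("NR52", u, "bsc"),
               (12 * 0.769 + 12 * 0.810 + 28 * 0.891) / 52)
  ones <- lapply(u, function(x) 1)
  expect_equal(year1_qaly("R52", ones, "dupilumab"), 1.0)
  expect_error(year1_qaly("R53", u, "bsc"), "unknown tree branch")
})

test_that("year-1 costs combine half-year cells, drug exposure and AE rates", {
  cfg <- base_config()
  tc <- cfg$tree_costs; drug <- cfg$drug_cost; ae <- cfg$adverse_events
  r52 <- year1_costs("R52", tc, drug, ae, "bsc")
  expect_equal(r52$therapy + r52$medical, 780 + 910 + 3345 + 3903)
  nr24 <- year1_costs("NR24", tc, drug, ae, "bsc")
  expect_equal(nr24$therapy + nr24$medical, 842 + 982 + 6790 + 7922)
  nr52 <- year1_costs("NR52", tc, drug, ae, "bsc")
  expect_equal(nr52$therapy + nr52$medical, 780 + 982 + 3345 + 7922)
  expect_equal(r52$drug_acquisition, 0)  # BSC acquisition is fixed at zero

  dup <- year1_costs("R52", tc, drug, ae, "dupilumab")
  expect_equal(dup$drug_acquisition,
               drug$price_per_administration * 26 * drug$compliance)
  early_stop <- year1_costs("NR24", tc, drug, ae, "dupilumab")
  expect_equal(early_stop$drug_acquisition,
               drug$price_per_administration * 26 * drug$compliance * 24 / 52)
  expect_equal(dup$adverse_events, annual_ae_cost(ae, "dupilumab"))

  drug0 <- drug; drug0$price_per_administration <- 0
  expect_equal(year1_costs("R52", tc, drug0, ae, "dupilumab")$drug_acquisition, 0)
  drugNA <- drug; drugNA$price_per_administration <- NA_real_
  expect_error(year1_costs("R52", tc, drugNA, ae, "dupilumab"),
               "price per administration")
})

test_that("the tree outcome is the probability-weighted branch expectation", {
  cfg <- base_config()
  out <- run_tree(cfg, "dupilumab")
  expect_equal(sum(out$branches$probability), 1)
  expect_equal(sum(out$entry), 1)
  expect_equal(out$qaly, sum(out$branches$probability * out$branches$qaly))
  expect_equal(out$costs$drug_acquisition,
               sum(out$branches$probability * out$branches$drug_acquisition))

  # universal response: everyone enters Controlled disease
  c1 <- cfg
  c1$response[c("p_resp_wk24_dup", "p_resp_wk52_given_wk24_dup")] <- list(1, 1)
  expect_equal(run_tree(c1, "dupilumab")$entry[["CONTROLLED"]], 1)

  # universal failure: the eligibility split applies to all mass
  c0 <- cfg
  c0$response$p_resp_wk24_bsc <- 0
  e <- run_tree(c0, "bsc")$entry
  expect_equal(e[["INADEQ_ELIG"]], 0.849)
  expect_equal(e[["INADEQ_INELIG"]], 0.151)

  # expected year-1 QALYs are monotone in response when responders do better
  c_hi <- cfg
  c_hi$response$p_resp_wk24_dup <- min(1, cfg$response$p_resp_wk24_dup + 0.2)
  expect_gt(run_tree(c_hi, "dupilumab")$qaly, out$qaly)

  # identical inputs across arms differ only through the week 12-24 utility
  c_eq <- cfg
  c_eq$response$p_resp_wk24_bsc <- cfg$response$p_resp_wk24_dup
  c_eq$response$p_resp_wk52_given_wk24_bsc <- cfg$response$p_resp_wk52_given_wk24_dup
  q_dup <- run_tree(c_eq, "dupilumab")$qaly
  q_bsc <- run_tree(c_eq, "bsc")$qaly
  expect_equal(q_dup - q_bsc, 12 * (0.875 - 0.810) / 52)
})
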