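# Year 1: decision tree with response assessments at weeks 24 and 52.
# Three terminal branches per arm:
#   NR24 - non-responder at week 24 (discontinues active treatment),
#   NR52 - responder at week 24 who fails the week-52 assessment,
#   R52  - responder at both assessments (enters "Controlled disease").

.tree_branches <- c("NR24", "NR52", "R52")

#' Decision-tree branch probabilities for one arm
#'
#' The week-52 probability is conditional on week-24 response, because only
#' week-24 responders remain in the tree to be re-assessed.
#'
#' @param resp list with `p_resp_wk24_*` and `p_resp_wk52_given_wk24_*`
#' @param arm `"dupilumab"` or `"bsc"`
#' @return named numeric vector over `NR24`, `NR52`, `R52`, summing to 1
#' @export
branch_probabilities <- function(resp, arm) {
  sfx <- switch(arm, dupilumab = "dup", bsc = "bsc",
                stopf("unknown arm label: %s", arm))
  p24 <- resp[[paste0("p_resp_wk24_", sfx)]]
  p52 <- resp[[paste0("p_resp_wk52_given_wk24_", sfx)]]
  c(NR24 = 1 - p24, NR52 = p24 * (1 - p52), R52 = p24 * p52)
}

#' Helper: convert a marginal week-52 response rate to the conditional scale
#'
#' If a source reports the week-52 responder share of the whole arm rather
#' than of week-24 responders, divide by the week-24 rate.
#'
#' @param p52_marginal week-52 responder proportion of the full arm
#' @param p24 week-24 responder proportion
#' @return week-52 probability conditional on week-24 response
#' @export
conditional_from_marginal <- function(p52_marginal, p24) {
  if (p24 <= 0) stopf("p24 must be positive to condition on it")
  if (p52_marginal > p24) stopf("marginal week-52 rate cannot exceed the week-24 rate")
  p52_marginal / p24
}

#' Expected year-1 QALYs for one tree branch
#'
#' Time-weighted utility over the 52 weeks: baseline utility for weeks 0-12,
#' the treatment-specific utility for weeks 12-24, and the responder or
#' non-responder utility for the remaining 28 weeks. Week-52 failures (NR52)
#' carry responder utility through weeks 24-52: their loss of response is only
#' detected at the week-52 assessment.
#'
#' @param branch one of `"NR24"`, `"NR52"`, `"R52"`
#' @param u tree utility set
#' @param arm arm label
#' @return QALYs accrued in year 1 (undiscounted)
#' @export
year1_qaly <- function(branch, u, arm) {
  u1224 <- switch(arm, dupilumab = u$u_wk12_24_dup, bsc = u$u_wk12_24_bsc,
                  stopf("unknown arm label: %s", arm))
  u_after <- switch(branch,
    NR24 = u$u_wk24plus_nonresponder,
    NR52 = u$u_wk24plus_responder,
    R52  = u$u_wk24plus_responder,
    stopf("unknown tree branch: %s", branch))
  (12 * u$u_baseline + 12 * u1224 + 28 * u_after) / 52
}

#' Year-1 costs for one tree branch
#'
#' Therapy and medical costs are read from the half-year cost table by the
#' branch's response status in each half (NR24: non-responder costs both
#' halves; NR52: responder costs weeks 0-24 then non-responder costs weeks
#' 25-52; R52: responder costs both halves). Drug acquisition applies to the
#' dupilumab arm only: price times 26 administrations times compliance, scaled
#' by the on-treatment fraction of the year (week-24 failures stop at 24/52).
#' Adverse-event costs are one year at the arm's annual rate.
#'
#' @param branch branch label
#' @param tc tree cost table (responder/nonresponder half-year cells)
#' @param drug drug-cost specification
#' @param ae adverse-event profile
#' @param arm arm label
#' @return list with `therapy`, `medical`, `drug_acquisition`,
#'   `adverse_events` (EUR)
#' @export
year1_costs <- function(branch, tc, drug, ae, arm) {
  status <- switch(branch,
    NR24 = c("nonresponder", "nonresponder"),
    NR52 = c("responder", "nonresponder"),
    R52  = c("responder", "responder"),
    stopf("unknown tree branch: %s", branch))
  h1 <- tc[[status[1L]]]; h2 <- tc[[status[2L]]]
  therapy <- h1$therapy_wk0_24 + h2$therapy_wk25_52
  medical <- h1$medical_wk0_24 + h2$medical_wk25_52
  if (arm == "dupilumab") {
    price <- drug$price_per_administration
    if (is.null(price) || is.na(price))
      stopf("drug price per administration is required for the dupilumab arm")
    frac <- if (branch == "NR24") 24 / 52 else 1
    drug_acq <- price * drug$administrations_per_year * drug$compliance * frac
  } else if (arm == "bsc") {
    drug_acq <- drug$bsc_acquisition_cost
  } else stopf("unknown arm label: %s", arm)
  list(therapy = therapy, medical = medical, drug_acquisition = drug_acq,
       adverse_events = annual_ae_cost(ae, arm))
}

#' Run the year-1 decision tree for one arm
#'
#' Produces the branch table, the probability-weighted year-1 QALYs and cost
#' breakdown, and the distribution over Markov entry states at year end:
#' week-52 responders enter "Controlled disease", all non-responders enter
#' "Inadequately controlled disease", split into surgery-eligible and
#' -ineligible sub-states. Year-1 quantities are undiscounted (year 1 is
#' time zero) and no mortality is applied within the tree.
#'
#' @param cfg a validated `cua_config`
#' @param arm arm label
#' @return object of class `tree_outcome`
#' @export
run_tree <- function(cfg, arm) {
  pr <- branch_probabilities(cfg$response, arm)
  rows <- lapply(.tree_branches, function(b) {
    cost <- year1_costs(b, cfg$tree_costs, cfg$drug_cost,
                        cfg$adverse_events, arm)
    data.frame(branch = b, probability = pr[[b]],
               qaly = year1_qaly(b, cfg$tree_utilities, arm),
               therapy = cost$therapy, medical = cost$medical,
               drug_acquisition = cost$drug_acquisition,
               adverse_events = cost$adverse_events,
               stringsAsFactors = FALSE)
  })
  branches <- do.call(rbind, rows)
  w <- branches$probability
  costs <- list(
    therapy = sum(w * branches$therapy),
    medical = sum(w * branches$medical),
    drug_acquisition = sum(w * branches$drug_acquisition),
    adverse_events = sum(w * branches$adverse_events))
  p_inel <- cfg$surgery_access$p_ineligible
  nonresp <- pr[["NR24"]] + pr[["NR52"]]
  entry <- c(CONTROLLED = pr[["R52"]],
             INADEQ_ELIG = nonresp * (1 - p_inel),
             INADEQ_INELIG = nonresp * p_inel,
             SURGERY = 0, POSTOP_CONTROLLED = 0, POSTOP_UNCONTROLLED = 0,
             DEATH = 0)
  structure(list(arm = arm, branches = branches,
                 qaly = sum(w * branches$qaly), costs = costs,
                 entry = entry),
            class = "tree_outcome")
}

#' @export
print.tree_outcome <- function(x, ...) {
  cat(sprintf("Year-1 decision tree, %s arm\n", x$arm))
  print(x$branches, row.names = FALSE)
  cat(sprintf("Expected year-1 QALYs: %.4f\n", x$qaly))
  invisible(x)
}
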