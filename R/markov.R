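# Lifetime Markov cohort model, annual cycles.
#
# States: Controlled disease; Inadequately controlled disease, split into
# surgery-eligible and -ineligible sub-states (eligibility is a persistent
# attribute of 15.1% of the uncontrolled population); Surgery (one-cycle
# tunnel); Post-operative controlled; Post-operative uncontrolled; Death.
# Death is applied first each cycle from the age-specific background hazard;
# clinical transitions act on survivors.

#' Health states of the Markov model
#' @return character vector of state labels
#' @export
health_states <- function() {
  c("CONTROLLED", "INADEQ_ELIG", "INADEQ_INELIG", "SURGERY",
    "POSTOP_CONTROLLED", "POSTOP_UNCONTROLLED", "DEATH")
}

# Clinical (conditional-on-survival) transition matrix at a given age.
clinical_matrix <- function(cfg, age) {
  s <- health_states()
  M <- matrix(0, 7, 7, dimnames = list(s, s))
  sa <- cfg$surgery_access
  p_sus <- cfg$sustained_response$annual_p_sustain
  eligible_age <- floor(age) < sa$max_surgery_age
  p_surg <- if (eligible_age) sa$annual_p_surgery else 0
  M["CONTROLLED", "CONTROLLED"] <- p_sus
  M["CONTROLLED", "INADEQ_ELIG"] <- (1 - p_sus) * (1 - sa$p_ineligible)
  M["CONTROLLED", "INADEQ_INELIG"] <- (1 - p_sus) * sa$p_ineligible
  M["INADEQ_ELIG", "SURGERY"] <- p_surg
  M["INADEQ_ELIG", "INADEQ_ELIG"] <- 1 - p_surg
  M["INADEQ_INELIG", "INADEQ_INELIG"] <- 1
  M["SURGERY", "POSTOP_CONTROLLED"] <- sa$p_surgery_to_postop_controlled
  M["SURGERY", "POSTOP_UNCONTROLLED"] <- 1 - sa$p_surgery_to_postop_controlled
  M["POSTOP_CONTROLLED", "POSTOP_CONTROLLED"] <- 1 - sa$p_postop_to_uncontrolled
  M["POSTOP_CONTROLLED", "POSTOP_UNCONTROLLED"] <- sa$p_postop_to_uncontrolled
  M["POSTOP_UNCONTROLLED", "SURGERY"] <- p_surg
  M["POSTOP_UNCONTROLLED", "POSTOP_UNCONTROLLED"] <- 1 - p_surg
  M["DEATH", "DEATH"] <- 1
  M
}

#' One-cycle transition probabilities out of a state
#'
#' Background mortality at the (floored) age is applied first; the surviving
#' mass is distributed by the clinical transition rules. Surgery is offered
#' only below the maximum surgical age.
#'
#' @param state a label from [health_states()]
#' @param age cohort age during the cycle (fractional allowed; floored for
#'   the mortality lookup and the surgical age cutoff)
#' @param cfg a `cua_config`
#' @param lt a `life_table`
#' @return named probability vector over all states, summing to 1
#' @export
transition_row <- function(state, age, cfg, lt) {
  s <- health_states()
  if (!state %in% s) stopf("unknown health state: %s", state)
  q <- q_at(lt, age)
  row <- (1 - q) * clinical_matrix(cfg, age)[state, ]
  row["DEATH"] <- row["DEATH"] + q
  row
}

#' Advance the cohort by one annual cycle
#'
#' @param occupancy named occupancy vector over [health_states()], summing
#'   to 1
#' @param age cohort age during the cycle
#' @param cfg a `cua_config`
#' @param lt a `life_table`
#' @return list with `occupancy` (next cycle) and `surgery_entries` (the
#'   proportion of the cohort entering the Surgery tunnel this cycle)
#' @export
step <- function(occupancy, age, cfg, lt) {
  if (abs(sum(occupancy) - 1) > 1e-9)
    stopf("occupancy must sum to 1 (got %.12f)", sum(occupancy))
  q <- q_at(lt, age)
  C <- clinical_matrix(cfg, age)
  nxt <- (1 - q) * as.numeric(occupancy %*% C)
  names(nxt) <- health_states()
  nxt["DEATH"] <- nxt["DEATH"] + q * sum(occupancy)
  list(occupancy = nxt,
       surgery_entries = (1 - q) * sum(occupancy * C[, "SURGERY"]))
}

#' Run the Markov cohort model to the horizon
#'
#' Iterates annual cycles from cohort age `start_age + 1`, recording state
#' occupancy and the flow into the Surgery tunnel each cycle, until the
#' horizon age is reached or the alive mass falls below 1e-9. The final life
#' table age is absorbing (q = 1), so the trace always terminates.
#'
#' @param entry distribution over [health_states()] at the end of year 1
#' @param cfg a `cua_config`
#' @param lt a `life_table`
#' @return object of class `cohort_trace`: occupancy matrix (cycles x
#'   states) with attached ages, surgery-entry flows and alive mass
#' @export
run_markov <- function(entry, cfg, lt) {
  s <- health_states()
  if (abs(sum(entry) - 1) > 1e-9) stopf("entry distribution must sum to 1")
  start_age <- cfg$demographics$start_age
  horizon <- min(cfg$econ$horizon_max_age, lt$ages[length(lt$ages)])
  if (horizon <= start_age) stopf("horizon_max_age must exceed start_age")
  k_max <- max(1L, floor(horizon - start_age + 1))
  occ <- matrix(NA_real_, k_max, 7, dimnames = list(NULL, s))
  surg <- numeric(k_max); ages <- numeric(k_max)
  cur <- entry[s]
  k <- 0L
  while (k < k_max) {
    age <- start_age + k + 1
    if (floor(age) > horizon) break
    st <- step(cur, age, cfg, lt)
    k <- k + 1L
    occ[k, ] <- st$occupancy
    surg[k] <- st$surgery_entries
    ages[k] <- age
    cur <- st$occupancy
    if (1 - cur[["DEATH"]] < 1e-9) break
  }
  structure(list(cycle = seq_len(k), age = ages[seq_len(k)],
                 occupancy = occ[seq_len(k), , drop = FALSE],
                 surgery_entries = surg[seq_len(k)],
                 alive = 1 - occ[seq_len(k), "DEATH"],
                 entry = entry[s]),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: %d annual cycles, ages %.2f-%.2f\n",
              length(x$cycle), x$age[1L], x$age[length(x$age)]))
  cat(sprintf("Alive mass at final cycle: %.3g\n",
              x$alive[length(x$alive)]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  d <- data.frame(cycle = x$cycle, age = x$age)
  d <- cbind(d, as.data.frame(x$occupancy))
  d$surgery_entries <- x$surgery_entries
  d$alive_mass <- x$alive
  d
}
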