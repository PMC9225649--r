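# Independent Monte-Carlo microsimulation of the Markov rules, hand-coded
# from the configuration parameters (it deliberately does not call the
# package's transition machinery). Simulates N individuals year by year and
# returns per-cycle state occupancy proportions.

microsim_trace <- function(cfg, entry, lt, n_cycles, N = 200000, seed = 20) {
  set.seed(seed)
  s <- c("CONTROLLED", "INADEQ_ELIG", "INADEQ_INELIG", "SURGERY",
         "POSTOP_CONTROLLED", "POSTOP_UNCONTROLLED", "DEATH")
  counts <- as.vector(stats::rmultinom(1, N, entry[s]))
  state <- rep.int(seq_along(s), counts)
  start_age <- cfg$demographics$start_age
  sa <- cfg$surgery_access
  p_sus <- cfg$sustained_response$annual_p_sustain
  p_inel <- sa$p_ineligible
  occ <- matrix(0, n_cycles, 7, dimnames = list(NULL, s))
  for (k in seq_len(n_cycles)) {
    age <- start_age + k
    q <- lt$q[floor(age) - lt$ages[1L] + 1L]
    can_operate <- floor(age) < sa$max_surgery_age
    p_surg <- if (can_operate) sa$annual_p_surgery else 0
    alive <- state != 7L
    dies <- alive & (stats::runif(length(state)) < q)
    state[dies] <- 7L
    r <- stats::runif(length(state))
    new <- state
    i <- state == 1L
    new[i & r < p_sus] <- 1L
    new[i & r >= p_sus & r < p_sus + (1 - p_sus) * (1 - p_inel)] <- 2L
    new[i & r >= p_sus + (1 - p_sus) * (1 - p_inel)] <- 3L
    i <- state == 2L
    new[i] <- ifelse(r[i] < p_surg, 4L, 2L)
    i <- state == 4L
    new[i] <- ifelse(r[i] < sa$p_surgery_to_postop_controlled, 5L, 6L)
    i <- state == 5L
    new[i] <- ifelse(r[i] < sa$p_postop_to_uncontrolled, 6L, 5L)
    i <- state == 6L
    new[i] <- ifelse(r[i] < p_surg, 4L, 6L)
    state <- new
    occ[k, ] <- tabulate(state, 7L) / N
  }
  occ
}
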