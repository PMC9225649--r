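# Shared fixtures, all built in code.

base_config <- function(seed = 1L) default_fixture(seed)$config

base_life_table <- function() default_fixture(1L)$life_table

# Artificial schedule with no background mortality below the final age;
# used for closed-form checks (geometric decay, undiscounted sums).
zero_mortality_lt <- function(max_age = 200L) {
  q <- rep(0, max_age + 1L)
  q[max_age + 1L] <- 1
  life_table(0:max_age, q, strict = FALSE)
}

# Configuration whose Markov phase runs exactly `cycles` annual cycles with
# no deaths: integer start age, horizon start_age + cycles.
finite_horizon_config <- function(cycles = 10, start_age = 50) {
  cfg <- base_config()
  cfg$demographics$start_age <- start_age
  cfg$econ$horizon_max_age <- start_age + cycles
  cfg
}
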