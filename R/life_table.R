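# Background mortality: annual death probabilities by single year of age.
# The cohort model needs a complete schedule up to an absorbing final age;
# a parametric Gompertz-Makeham generator provides one offline.

#' Construct a life table
#'
#' @param ages contiguous integer ages
#' @param q annual death probability per age; the final age must be 1
#'   (absorbing horizon)
#' @param strict if `TRUE` (the default for file input and the generator),
#'   require `q > 0` everywhere; artificial schedules used in closed-form
#'   checks may set `strict = FALSE` to allow zero mortality.
#' @return object of class `life_table`
#' @export
life_table <- function(ages, q, strict = TRUE) {
  ages <- as.integer(ages)
  if (length(ages) != length(q)) stopf("ages and q differ in length")
  if (any(diff(ages) != 1L)) stopf("ages must be contiguous")
  if (any(q < 0) || any(q > 1)) stopf("q must lie in [0, 1]")
  if (strict && any(q <= 0)) stopf("q must be strictly positive at every age")
  if (q[length(q)] != 1) stopf("q at the final age must be 1")
  structure(list(ages = ages, q = as.numeric(q)), class = "life_table")
}

#' Generate a synthetic life table from a Gompertz-Makeham hazard
#'
#' Annual death probability `q(age) = 1 - exp(-(a + b * exp(c * age)))`,
#' clamped to at most 1, with `q` forced to 1 at `max_age`. The defaults give
#' a life expectancy at birth of about 82.8 years, matching a Western-European
#' (Italian-style) general population. The schedule is deterministic.
#'
#' @param makeham_a age-independent hazard component (per year)
#' @param gompertz_b baseline senescent hazard (per year)
#' @param gompertz_c exponential ageing rate (1/year)
#' @param min_age,max_age integer age range
#' @return a `life_table`
#' @export
generate_gompertz_makeham <- function(makeham_a = 5e-4, gompertz_b = 2.5e-5,
                                      gompertz_c = 0.09,
                                      min_age = 0, max_age = 110) {
  if (makeham_a < 0 || gompertz_b <= 0 || gompertz_c <= 0)
    stopf("require makeham_a >= 0, gompertz_b > 0, gompertz_c > 0")
  if (min_age >= max_age) stopf("min_age must be below max_age")
  ages <- seq.int(min_age, max_age)
  h <- makeham_a + gompertz_b * exp(gompertz_c * ages)
  q <- pmin(1, 1 - exp(-h))
  if (any(q[ages < 100] >= 1))
    warning("hazard parameters yield certain death before age 100")
  q[length(q)] <- 1
  life_table(ages, q)
}

#' Annual death probability at a (possibly fractional) age
#'
#' Ages are floored to whole years for lookup; the cohort's fractional start
#' age advances by exactly one year per cycle, so the lookup is deterministic.
#'
#' @param lt a `life_table`
#' @param age age in years, possibly fractional
#' @return probability of death within the year
#' @export
q_at <- function(lt, age) {
  a <- floor(age)
  idx <- a - lt$ages[1L] + 1L
  if (any(idx < 1L) || any(idx > length(lt$q)))
    stopf("age %s outside the life table range [%d, %d]",
          paste(age, collapse = ", "), lt$ages[1L], lt$ages[length(lt$ages)])
  lt$q[idx]
}

#' Read a life table from CSV
#'
#' Expects columns `age` and `qx`; validates contiguity and probability
#' bounds.
#'
#' @param path CSV file path
#' @return a `life_table`
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(d)))
    stopf("life-table file must have columns 'age' and 'qx'")
  life_table(d$age, d$qx)
}

#' @rdname read_life_table
#' @param lt a `life_table`
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(data.frame(age = lt$ages, qx = lt$q), path,
                   row.names = FALSE)
  invisible(path)
}

# Resolve the life-table reference stored in a configuration.
resolve_life_table <- function(cfg) {
  ref <- cfg$life_table
  if (inherits(ref, "life_table")) return(ref)
  switch(ref$type,
    gompertz_makeham = generate_gompertz_makeham(
      ref$makeham_a, ref$gompertz_b, ref$gompertz_c,
      ref$min_age %||% 0, ref$max_age %||% 110),
    file = read_life_table(ref$path),
    stopf("unknown life-table reference type: %s", ref$type))
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages %d-%d, q(%d) = %.5f, final age absorbing\n",
              x$ages[1L], x$ages[length(x$ages)], x$ages[1L], x$q[1L]))
  invisible(x)
}
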