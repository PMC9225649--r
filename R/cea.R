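# Incremental analysis: ICUR, dominance, net monetary benefit.

#' Incremental cost-utility ratio of intervention vs comparator
#'
#' Computes incremental costs and QALYs and classifies dominance: the
#' intervention dominates when it gains QALYs at no extra cost; the comparator
#' dominates in the mirror case. A bare ratio is reported only in the
#' north-east quadrant (more costly, more effective); the cost-saving,
#' QALY-losing quadrant keeps its ratio but is explicitly labelled, since a
#' "low" ICUR there is unfavourable. Zero incremental QALYs with non-zero
#' incremental cost yields an undefined-ratio signal, reported rather than
#' thrown.
#'
#' @param intervention,comparator `cua_arm` results from the same
#'   configuration and horizon
#' @return object of class `cea_result` with `delta_cost`, `delta_qaly`,
#'   `icur`, `dominance` and a human-readable `status`
#' @export
icur <- function(intervention, comparator) {
  dc <- intervention$costs$total - comparator$costs$total
  dq <- intervention$qalys - comparator$qalys
  dominance <- "none"; value <- NA_real_; status <- "ratio"
  if (dq == 0 && dc == 0) {
    status <- "indifferent"
  } else if (dq == 0) {
    status <- "undefined ratio (zero incremental QALYs)"
  } else if (dq > 0 && dc <= 0) {
    dominance <- "intervention_dominates"; status <- "intervention dominates"
  } else if (dq < 0 && dc >= 0) {
    dominance <- "comparator_dominates"; status <- "comparator dominates"
  } else {
    value <- dc / dq
    if (dq < 0 && dc < 0)
      status <- "cost-saving, QALY-losing quadrant (ratio not directly comparable)"
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icur = value,
                 dominance = dominance, status = status),
            class = "cea_result")
}

#' Net monetary benefit of one arm at a willingness-to-pay threshold
#'
#' @param result a `cua_arm`
#' @param wtp willingness to pay, EUR per QALY (non-negative)
#' @return `wtp * QALYs - total cost`, in EUR
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) stopf("willingness to pay must be non-negative")
  wtp * result$qalys - result$costs$total
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Incremental cost:  EUR %.0f\n", x$delta_cost))
  cat(sprintf("Incremental QALYs: %.2f\n", x$delta_qaly))
  if (!is.na(x$icur))
    cat(sprintf("ICUR: EUR %.0f per QALY gained\n", x$icur))
  cat(sprintf("Status: %s\n", x$status))
  invisible(x)
}
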