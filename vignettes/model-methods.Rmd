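---
title: "A decision-tree/Markov cost-utility model of dupilumab in severe CRSwNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree/Markov cost-utility model of dupilumab in severe CRSwNP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupcua)
```

## The decision problem

Severe uncontrolled chronic rhinosinusitis with nasal polyps (CRSwNP) is
managed with best supportive care (BSC: intranasal/oral corticosteroids,
saline irrigation, and endoscopic sinus surgery when medical therapy fails).
Dupilumab, an anti-IL-4Rα monoclonal antibody given subcutaneously at 300 mg
every two weeks, is the first biologic licensed for this indication. The
package asks the standard health-economic question: per patient, over a
lifetime, what do the extra drug costs buy in quality-adjusted life years
(QALYs), and is the incremental cost-utility ratio (ICUR = ΔCost/ΔQALY)
acceptable at Italian willingness-to-pay levels (informally €25,000–€40,000
per QALY, midpoint €32,500)?

## Model structure

**Year 1 — decision tree.** All patients start treatment (dupilumab + BSC,
or BSC alone). Response — a composite of SNOT-22 improvement ≥ 8.9 points
and nasal polyp score improvement ≥ 1 — is assessed at week 24;
week-24 responders are re-assessed at week 52. This yields three branches
per arm: failure at 24 weeks (NR24), failure at 52 weeks (NR52), sustained
response (R52). Year-1 QALYs time-weight four utility values (baseline
0.769 for weeks 0–12; treatment-specific 0.875/0.810 for weeks 12–24;
responder 0.891 / non-responder 0.808 thereafter); year-1 costs combine
half-year therapy and medical cost cells, drug acquisition (week-24 failures
receive 24/52 of the year's 26 administrations), and annual adverse-event
costs.

**Years 2+ — Markov cohort model, annual cycles.** Week-52 responders enter
*Controlled disease*; all failures enter *Inadequately controlled disease*,
split once into surgery-eligible (84.9%) and -ineligible (15.1%)
sub-states — eligibility is modelled as a persistent attribute, and mass
discontinuing from Controlled disease (2%/year, i.e. a 98% sustained
response) re-enters the same split, so patients can undergo multiple
surgeries. Eligible uncontrolled patients move to *Surgery* at 1.9%/year
while younger than 70 (ages are floored for both the cutoff and the
mortality lookup). Surgery is a one-cycle tunnel into *Post-operative
controlled*, which relapses to *Post-operative uncontrolled* at 40%/year;
relapsed patients can be re-operated at the same 1.9%/year. Death, from an
age-specific background schedule, is reachable from every state, is applied
first each cycle (clinical transitions act on survivors), and is the only
exit whose rate depends on age — which is why the alive mass equals the
survival product `Π(1 − q(age))`, a property the tests assert exactly.

**Valuation.** Year 1 is time zero and undiscounted; cycle *k* is discounted
by `(1 + r)^−k` with r = 3% for both costs and effects. QALYs weight state
occupancy by the Markov utility set (0.913 controlled, 0.776 inadequately
controlled, 0.820 surgery, 0.827 = 0.776 + 0.051 post-operative controlled,
0.760 post-operative uncontrolled). Costs accrue per cycle: drug
acquisition (price × 26 × compliance) on Controlled occupancy in the
dupilumab arm only; disease-management costs (€8,937 controlled-type states,
€16,536 uncontrolled-type states — US estimates converted at PPP 0.648) on
occupancy; a €2,113 surgery episode (€104 CT + €2,009 procedure) on the flow
entering the tunnel, and €103/year follow-up (5 visits × €20.66, rounded) on
post-operative occupancy; adverse-event costs on the alive mass at
arm-specific annual rates; and, under the societal perspective, productivity
losses (workdays lost × 8 h × €29.80/h) on occupancy.

## What is published and what is synthetic

Four inputs the model needs are not published numerically, and the package
treats them as first-class synthetic placeholders rather than guessing at
source values. Every one is provenance-tagged, every report watermarks them,
and `perturb_fixture()` jitters exactly these values for robustness checks:

* **Response probabilities** (weeks 24 and 52, both arms): published only
  graphically. Stored as (week-24 marginal, week-52 conditional on week-24
  response) because only week-24 responders are re-assessed;
  `conditional_from_marginal()` converts sources reported the other way.
  Placeholders: dupilumab 0.60 then 0.90; BSC 0.25 then 0.65 — mid-range
  values with the right ordering, chosen once.
* **Mortality**: the source describes no life table. The generator uses a
  Gompertz–Makeham hazard, `q(age) = 1 − exp(−(a + b·e^{c·age}))` with
  a = 5·10⁻⁴, b = 2.5·10⁻⁵, c = 0.09 over ages 0–110, chosen once to give
  life expectancy at birth ≈ 82.8 years (Italian-style); the final age is
  forced absorbing. Users can substitute any national table via a CSV of
  `age,qx`.
* **Drug price per administration**: the net ex-factory price is
  confidential; the configuration constructor deliberately has no default.
  The fixture's placeholder (€580) is list-price scale only. Users with the
  published lifetime discounted drug cost (€76,383) can back-solve a price
  under their own assumptions; the package does not do this silently.
* **Workdays lost per state** (societal scenario only): not published; the
  defaults (1 day/year in controlled-type states, 6 in uncontrolled-type
  states, 10 in the surgery year) keep the uncontrolled-minus-controlled
  gap at the scale of published CRS absenteeism (≈ 5 days/year).

Because the first three placeholders drive the absolute results, the
package's headline numbers are *not* reproductions of any published
estimate, and the reports say so. What the model does reproduce — and what
the test suite pins down — are the structural and arithmetic properties:
conservation of cohort mass, the closed-form geometric decays, the survival
product, the published cost-table identities, and the directions of the
scenario effects.

## Sensitivity analysis

**One-way (tornado).** Each parameter in turn is set to its lower and upper
bound (default ±10%, probabilities clamped to [0, 1]; 95% CIs can be
supplied where known), the whole pipeline is re-run, and parameters are
ranked by the ICUR span. The base configuration is restored between runs,
so run order is irrelevant — a property the tests check by permuting.

**Probabilistic.** Parameters are sampled independently: gamma for costs
and resource use, beta for probabilities/proportions/adverse-event rates,
normal truncated to [0, 1] for utilities, all moment-matched
(gamma: shape = (m/s)², scale = s²/m; beta: α = m·ν, β = (1−m)·ν with
ν = m(1−m)/s² − 1). Standard errors default to 10% of the mean, mirroring
the one-way rule, because the source states families but no SEs.
Structurally fixed quantities (discount rates, the horizon, the age-70
cutoff, certain/impossible transitions, compliance) are excluded from the
PSA but the rates appear in the one-way analysis. One caveat the tests make
explicit: truncating a normal at 1 shifts its realised mean below the
nominal mean (for u = 0.913, s = 0.0913 the shift is ≈ −0.03), so utility
draws are systematically slightly conservative; the parameter-recovery test
therefore checks the truncated distribution's own closed-form moments.
A single seed drives one RNG stream through all sampling; identical seeds
give bit-identical results.

**Scenarios.** `scenario_compliance(cfg, 0.9695)` scales only the drug-cost
pathway (QALYs provably unchanged, ICUR strictly lower whenever ΔQALY > 0);
`scenario_societal(cfg)` flips the perspective switch so indirect costs
accrue — total costs change by exactly the indirect component.

## Numerical choices and conventions

* Annual cycles, no half-cycle correction by default (the published
  probabilities are annual and the source is silent on correction); the
  standard correction — averaging each cycle's start and end occupancy — is
  available as `econ$half_cycle_correction`.
* No deaths and no surgery inside year 1: the tree describes neither; the
  Markov surgery rate is the only quantified route and begins in cycle 1.
* NR52 patients accrue responder *utility* for weeks 24–52 (loss of
  response is detected only at the week-52 assessment) but non-responder
  *costs* for weeks 25–52; both conventions are explicit switches.
* The €103/year follow-up is added on top of the post-operative state cost,
  since it is priced separately from the disease-management estimates; a
  switch folds it in for users who read the state costs as all-inclusive.
* The run stops at the life-table horizon (age 110, absorbing) or when the
  alive mass falls below 10⁻⁹; with the default fixture the Markov phase is
  59 cycles, and a full two-arm fit takes ~10 ms, so the default analysis
  sizes (1,000 PSA draws, ~50-parameter tornado, a 200,000-individual
  microsimulation cross-check in the test suite) run comfortably on a
  laptop.
* Currency is carried at full double precision throughout and rounded only
  in printed reports (whole euros, QALYs to 2 decimals).

## Validation strategy

Internal validity is tested the way the field's good-practice guidelines
recommend: every transition row must be row-stochastic to 10⁻¹²; every
trace row must sum to 1 with monotone death occupancy; closed-form cases
(0.98^k decay, survival products, annuity-style discounted sums) must match
exactly; and an independent hand-coded Monte-Carlo microsimulation of
200,000 individuals must reproduce every trace cell within four binomial
standard errors. What the synthetic fixture cannot show is external
validity: absolute QALYs, costs and the ICUR depend on the placeholder
response rates and price, so agreement (or disagreement) with published
totals carries no evidential weight.

## A worked example

```{r example, eval = FALSE}
fx <- default_fixture(seed = 1)
fit <- cua(fx$config)
print(fit)
summary(fit)
ps <- simulate(fit, nsim = 1000)
head(ceac(ps, c(25000, 32500, 40000)))
```

## Known limitations

No sex-specific mortality (the cohort's 60.4% male fraction is carried but
plays no computational role); no disease-specific excess mortality; no
treatment re-challenge after discontinuation; no correlation between
sampled parameters in the PSA; no multi-comparator frontier (two arms
only); no cost indexation (tariffs are consumed as already inflated); and
no value-of-information analysis.
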