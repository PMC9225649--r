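# dupcua

A cost-utility model of dupilumab added to best supportive care (BSC)
versus BSC alone in adults with severe uncontrolled chronic rhinosinusitis
with nasal polyps (CRSwNP), from the Italian National Healthcare Service
perspective, with a societal-perspective option. It is written for health
economists and HTA analysts who want a transparent, fully tested, scriptable
re-implementation of this class of model rather than a spreadsheet.

## The model

A 1-year decision tree assesses treatment response (SNOT-22 improvement
≥ 8.9 and nasal polyp score improvement ≥ 1) at weeks 24 and 52, then hands
the cohort to a lifetime annual-cycle Markov model over six states:
Controlled disease, Inadequately controlled disease (surgery-eligible /
-ineligible sub-states), Surgery (one-cycle tunnel), Post-operative
controlled, Post-operative uncontrolled, and Death. Key published inputs:
98%/year sustained response; 15.1% surgery-ineligible; 1.9%/year surgery
below age 70; 40%/year post-operative relapse; two utility sets (tree and
Markov); Italian tariffs and PPP-converted disease-management costs; 3%
discounting of costs and effects.

Outputs are discounted QALYs and a cost breakdown per arm, and the
incremental cost-utility ratio

    ICUR = (C_dup − C_bsc) / (Q_dup − Q_bsc)   [EUR per QALY gained]

with net monetary benefit `NMB(λ) = λ·Q − C`, a ±10% one-way (tornado)
sensitivity analysis, a probabilistic sensitivity analysis with
moment-matched gamma/beta/truncated-normal distributions and
cost-effectiveness acceptability curves, and two scenario analyses
(societal perspective at €29.80/h; compliance 96.95%).

Four required inputs are not published numerically (arm-specific response
rates, the mortality schedule, the net drug price, workdays lost per
state). The package generates clearly watermarked synthetic placeholders
for them, so **absolute results do not reproduce any published estimate**;
the structural and arithmetic properties of the model are what the test
suite verifies. See `vignettes/model-methods.Rmd` for the full account.

## Worked example

```r
library(dupcua)
fx  <- default_fixture(seed = 1)   # published values + watermarked placeholders
fit <- cua(fx$config)
print(fit)
```

```
Cost-utility analysis: dupilumab + BSC vs BSC alone

                  outcome dupilumab+BSC     BSC difference
                    QALYs         17.52   16.71       0.81
   Drug acquisition (EUR)       134,561       0    134,561
 Disease management (EUR)       278,953 322,982    -44,029
     Adverse events (EUR)           742   1,406       -665
        Total costs (EUR)       414,256 324,388     89,868

ICUR: EUR 110,441 per QALY gained
Status: ratio

Note: 16 input(s) are synthetic or figure-only placeholders (see $watermark);
absolute results do not reproduce any published estimate.
```

Read it as: with the placeholder response rates and drug price, dupilumab
gains 0.81 discounted QALYs per patient over a lifetime; extra drug costs
(€134,561) are partly offset by €44,029 lower disease-management costs
(fewer uncontrolled years and surgeries) and slightly lower adverse-event
costs, for an ICUR of €110,441/QALY. The watermark note is the reminder
that these absolute numbers are placeholder-driven; swap in real response
rates, a national life table (`read_life_table()`) and the confidential
price to obtain decision-relevant values.

Sensitivity and scenarios:

```r
tor <- owsa(fit$config)                      # tornado, ±10% per parameter
ps  <- simulate(fit, nsim = 1000)            # probabilistic SA (seeded)
ceac(ps, c(25000, 32500, 40000))             # acceptability at Italian WTPs
cua(scenario_compliance(fx$config, 0.9695))  # compliance scenario
cua(scenario_societal(fx$config))            # societal perspective
```

A command-line wrapper is installed at `inst/cli/dupcua.R` with subcommands
`run`, `owsa`, `psa`, `scenario`, `fixtures`.

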