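---
title: "Model and methods: cost-effectiveness of ultrasound-guided central venous catheterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvccea)
```

## The decision problem

Central venous catheterization (CVC) of the internal jugular vein can be
performed under real-time two-dimensional ultrasound guidance (UG) or with
the classical landmark method (LM), in which the operator relies on surface
anatomy alone. Ultrasound visualization reduces both failed cannulation
attempts and mechanical complications — most prominently accidental arterial
puncture — but requires equipment and training. `cvccea` implements a
decision-analytic model that asks, from the perspective of the German
Statutory Health Insurance (SHI), whether UG is cost-effective relative to
LM when the payer bears the treatment costs of catheter-related
complications.

## The decision tree

Each strategy is evaluated on the same three-attempt tree. A patient
reaching attempt $k \in \{1,2,3\}$ first faces a total-complication chance
$c_k$; attempts 1 and 2 then split into success and failure with failure
probabilities $f_1$ and $f_2$, failures proceeding to the next attempt. The
third attempt concludes the episode whether or not cannulation succeeds —
the pathway allows at most three attempts, and the model does not resolve
the cannulation outcome of the final attempt.

The effectiveness outcome is person-level: a patient's event indicator is 1
if a complication occurred on *any* attempt reached, with complication
draws independent across attempts (no within-patient correlation structure
is published). The probability of at least one complication has the closed
form

$$
p_{\text{any}} \;=\; 1 - (1-c_1)\Bigl[(1-f_1) + f_1\,(1-c_2)\bigl((1-f_2) + f_2\,(1-c_3)\bigr)\Bigr],
$$

and effectiveness is $1 - p_{\text{any}}$ (per patient, "no complication"
is coded 1). We chose the person-level any-complication outcome rather than
an expected complication *count* because it is what reproduces the
published per-person figures (0.036 for UG, 0.175 for LM); the expected
count $c_1 + f_1 c_2 + f_1 f_2 c_3$ is used only on the cost side, where
every attempt-with-complication accrues cost.

Two implementations of the same semantics coexist deliberately:
`build_tree()` + `evaluate_tree()` perform an explicit expected-value
rollback over the enumerated tree, while `evaluate_strategy()` uses the
closed forms above. They agree to $10^{-12}$ and each is tested against a
patient-level microsimulation, so any future change that breaks one route
is caught by the others.

```{r base-case}
p <- default_parameters()
cea_table(p$ug, p$lm)
```

## Parameters

Clinical probabilities (per strategy, dimensionless):

| symbol | meaning | UG | LM |
|---|---|---|---|
| $f_1$ | failure on the first attempt | 0.164 | 0.376 |
| $f_2$ | failure on the second attempt | 0.049 | 0.166 |
| $c_1$ | total complications, attempt 1 | 0.029 | 0.114 |
| $c_2$ | total complications, attempt 2 | 0.041 | 0.156 |
| $c_3$ | total complications, attempt 3 | 0.047 | 0.177 |
| $a$ | arterial puncture, per attempt | 0.015 | 0.081 |

Each carries a 95% CI from the meta-analytic source data. The per-attempt
complication probabilities $c_2, c_3$ are pooled published values and are
used verbatim; the odds-ratio escalation mechanism reported for repeated
attempts (OR 8.4 and 35.6 vs the first attempt) is exposed as
`apply_odds_ratio()` for user scenarios, but applying those ORs to $c_1$
does not recover the published $c_2, c_3$ (e.g. UG $0.029 \to 0.2006$
against a published $0.041$), so it plays no part in the defaults.

Complication treatment costs (EUR 2016, per episode, SHI perspective):
arterial puncture 94, thrombosis 131, embolism 131, hydromediastinum 133,
hematomediastinum 94, hematothorax 177, hydrothorax 217, pneumothorax 178,
nerve injury 347, subcutaneous emphysema 16. Budget constants: 568,000
catheterizations/year, 10–20% UG adoption.

Derived spread parameters, and why:

* **SE from a CI.** The published inputs give only point estimates and 95%
  CIs, so the standard error is taken as CI width / 3.92 (normal
  approximation). This is the only spread information available.
* **Beta distributions for probabilities** by method of moments:
  $\nu = m(1-m)/s^2 - 1$, $\alpha = m\nu$, $\beta = (1-m)\nu$. The fit
  reproduces mean and variance exactly (tested to $10^{-9}$), and draws can
  never leave $[0,1]$, so the PSA needs no clamping.
* **Gamma distributions for costs**: shape $=(m/s)^2$, scale $=s^2/m$.
  Cost SEs are not published; the default is $s = 0.25\,m$, so the ±50%
  deterministic range corresponds to roughly ±2 SE. This is configurable
  per cost.
* **Composite weights.** No incidence breakdown within the "other
  complications" composite is published, so the nine non-arterial
  complications default to equal weights (1/9 each); the weights are a
  configuration knob for users with local incidence data.

## Cost attribution

The model prices a complication occurrence, not a specific diagnosis: the
expected cost of one occurrence is
$w_a \cdot \text{cost(arterial)} + (1-w_a)\sum_j w_j \,\text{cost}_j$,
where the arterial share $w_a = a / c_1$ (per-attempt arterial puncture
over first-attempt total complications, clamped to $[0,1]$; the reference
total is configurable). The within-composite split is a weight vector, not
a sub-tree, because no within-composite incidence is published. Expected
cost per person is then this unit cost times the expected number of
attempts-with-complication.

**Known limitation.** With the published per-complication costs this
yields roughly €4.5 (UG) and €20.7 (LM) per person — an order of magnitude
below the published €51/€230, whose reconciling inputs sit in an
unavailable supplement. The package therefore treats the cost side as
structural: all cost outputs are verified by properties (linearity in each
unit cost, zero cost under zero complication risk, microsimulation
agreement) rather than against the printed euro totals, the published
per-procedure saving of €179 is taken as an explicit *input* where a euro
figure is required (budget impact default, threshold analysis), and a
per-strategy `cost_multiplier` hook lets users calibrate the cost scale
without ever touching the effect side.

## Sensitivity analyses

**One-way deterministic (tornado).** Each probability is varied across its
95% CI and each cost across ±50%, all else at base, re-evaluating both
strategies. Because the base-case verdict is dominance, an ICER is
undefined in sign, so the tornado ranks parameters by the swing in
incremental cost (incremental-effect swings are reported side by side,
each with percent-of-base annotations); ties break alphabetically.
Probability bounds outside $[0,1]$ are clamped with a warning.

**Probabilistic (PSA).** 10,000 Monte Carlo iterations by default; every
probability is drawn from its beta and every cost from its gamma,
independently (no correlation structure is published). Costs are
model-wide parameters, so a single cost draw applies to both strategies
within an iteration. Summaries report means and 2.5th/97.5th percentiles
computed with the inclusive linear-interpolation definition (R quantile
type 7, recorded in the result), plus the fraction of iterations in which
UG dominates. An `se_scale` argument shrinks all spreads at once; at 0 the
PSA collapses to the base case, which anchors the convergence tests.

**Threshold.** UG intervention costs (equipment, training) are not
reimbursed by the SHI and are excluded from the base case. The break-even
analysis asks what per-procedure intervention cost would erase the cost
advantage: by linearity it is simply the negated base-case incremental
cost (€179 with the published input).

**Structural scenarios.** Higher-risk populations are emulated by
multiplying $c_1, c_2, c_3$ and $a$ (means and CIs) by a factor $m$,
leaving failure probabilities unchanged; probabilities are clamped at
0.999 with a warning. Multipliers act on probabilities, not odds, matching
the stated "doubling or tripling" of rates; neither choice exactly
reproduces the published doubled-rate per-person figures (probability
scaling gives ≈0.071/0.330 against printed 0.076/0.343, and the exact
doubling semantics are unstated), so scenario conclusions are checked as
verdicts and orderings, not values. Alternative populations (paediatric,
indirect cannulation) need meta-analytic inputs not printed with the
model, so they are supported as replacement parameter sets supplied via
configuration.

## Budget impact

Annual payer impact at adoption share $u$ is linear:
$u \times 568{,}000 \times$ (incremental cost or incremental effect).
Savings are reported to €0.1M and averted complications to the nearest
1,000. The incremental cost defaults to the published €−179; the
incremental effect defaults to the base case this package computes
(0.1383), which under 10–20% adoption rounds to the published 8,000–16,000
averted complications and €10.2–20.3M savings.

```{r budget}
budget_table(p$budget)
```

## The synthetic-data module

`simulate_cohort()` walks individual patients through the pathway
(per-attempt Bernoulli complication and failure draws, complication typing
from $(w_a, (1-w_a)w_j)$ with the type's cost accrued), and
`simulate_trial()` draws aggregate trial-like event tables whose
denominators follow the pathway (second-attempt outcomes among
first-attempt failures, and so on). `estimate_params()` closes the loop,
re-estimating probabilities as proportions with Wilson score CIs (via
`prop.test` without continuity correction; the method is recorded in the
result). Together these give every downstream stage a data source and an
independent oracle without any external data.

Cohorts are generated with vectorized draws in fixed patient order from a
single seeded stream: a given seed always reproduces the identical cohort.
(We considered per-patient counter-based substreams for order-independent
reproducibility, but R's RNG offers no cheap counterpart, and the seeded
contract is what the tests rely on.)

What the generator does and does not emulate: it realizes exactly the
tree's assumptions — independence of complications across attempts, a
homogeneous cohort, per-attempt probabilities constant across patients. It
does not model operator learning curves, anatomical covariates,
within-patient correlation, or catheter-related infections and mortality.
Passing round-trip tests therefore validates the implementation against
its own model, not the model against real patients.

## Numerical choices and test scale

* Branch probabilities must sum to 1 within $10^{-9}$ at every chance
  node; rollback vs closed form is asserted at $10^{-12}$.
* Moment-matching round trips (beta, gamma) are asserted at $10^{-9}$.
* Degenerate inputs: zero-width CIs give SE 0 and a parameter held fixed
  in the PSA; over-dispersed parameters ($s^2 \ge m(1-m)$) are rejected by
  the PSA with an error naming the parameter; $c_1 = 0$ sets the arterial
  share to 0.
* Test problem sizes: the microsimulation oracle runs once at $n = 10^6$
  against the base case and at $n = 10^4$ for each of 1,000 random
  parameter sets (three-Monte-Carlo-SE agreement, with the nominal ~99.7%
  3-SE coverage asserted as ≥99% across sets); parameter recovery uses
  1,000 trial replicates of $n = 10^5$ per arm with pooled Wilson coverage
  required in [93%, 97%]. These sizes make the binomial error small
  relative to the quantities checked while keeping the default test run
  fast.

## Reproducibility

`run_all()` executes every stage from one configuration (parameter file,
seed, PSA size, scenario list, output directory) and writes CSVs, a
machine-readable JSON of headline numbers — each emitted both unrounded
and at the published precision (costs to €1, probabilities to 3 decimals)
— and a human-readable log carrying the package version, seed and a
configuration hash. The same seed and configuration produce byte-identical
JSON.
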