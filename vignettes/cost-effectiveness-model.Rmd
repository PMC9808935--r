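---
title: "A decision tree plus nine-state Markov model for TAVI versus SAVR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision tree plus nine-state Markov model for TAVI versus SAVR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvecea)
```

## The decision problem

Severe aortic stenosis in elderly patients at high surgical risk can be
treated by open surgical aortic valve replacement (SAVR) or by transcatheter
aortic valve implantation (TAVI). TAVI is less invasive but far more
expensive in the Iranian payer context, where device prices are inflated by
exchange-rate pressure. `valvecea` implements a decision-analytic model
that asks whether TAVI's quality-of-life advantage justifies its extra cost
at willingness-to-pay (WTP) thresholds anchored on Iran's 2020 GDP per
capita (551,400,000 IRR per QALY for 1x, 1,654,200,000 for 3x, at 250,000
IRR per US$).

## Model structure

The model is a hybrid of a short-horizon decision tree and a lifetime
Markov cohort model.

**Entry stage (decision tree).** Each strategy's first-year outcomes are
collapsed into an entry distribution over five branches: NYHA functional
classes I--IV among survivors, and death from any cause. The published
trial probabilities are 0--12-month quantities while the tree nominally
covers thirty days, and no separate 30-day branch probabilities exist; we
therefore merge the tree with year one, applying the entry distribution at
the start of Markov cycle 1. Acute (procedure-phase) costs accrue here:
procedure, index hospitalization and device costs in full, plus
adverse-event management costs weighted by each event's probability.
Patients who die at entry accrue the full acute cost (they were operated
on) and zero QALYs.

**Lifetime stage (Markov).** Nine states: NYHA I--IV, the same four
classes after a disabling major stroke, and death, with one-year cycles.
Structural assumptions, each visible in `build_transition_matrix()`:

* every alive state shares the identical per-cycle all-cause death
  probability;
* surviving NYHA-*k* patients suffer a major stroke with the per-cycle
  stroke probability and move to the matching post-stroke state
  (competing risks compose multiplicatively: stroke applies to survivors,
  so rows sum to one exactly);
* the post-stroke compartment is absorbing among the alive states, and
  NYHA class itself is frozen -- the source evidence provides no
  inter-class transition probabilities;
* death is absorbing.

Rewards: state *s* earns its utility $u_s$ per cycle; post-stroke states
earn $\max(0, u_k - 0.39)$ from cycle 2 onward. The 0.39 major-stroke
disutility is deferred during the first cycle on the rehabilitation
argument (post-stroke rehabilitation preserves quality of life for about a
year). Whether the disutility should be subtractive or multiplicative is
not stated in the source evidence; we use absolute subtraction floored at
zero. Costs per cycle carry the expected recurring event costs -- by
default the annualized rehospitalization probability times the arm's
hospitalization cost (knob `rehospitalization_recurring`; the alternative
charges it once).

Discounting is end-of-cycle at 6.5% per year for both costs and effects:
cycle $t$ rewards are weighted $1/(1.065)^t$, so the value of one arm is

$$ V = C_{\text{acute}} + \sum_{t \ge 1} \frac{\langle \pi_{t-1},
   r_t\rangle}{(1+r)^{t}}, $$

with $\pi_t$ the occupancy row and $r_t$ the reward vector. A half-cycle
correction (trapezoid average of start- and end-of-cycle occupancy) is
available but off by default, mirroring the spreadsheet-style convention
of the original analysis. The cohort is propagated until survival drops
below `survival_stop_epsilon` ($10^{-4}$ by default -- the numeric reading
of "until nobody is left alive", which has no printed epsilon) or 50
cycles.

## Parameters and the configuration file

All parameters live in one YAML configuration
(`inst/extdata/model_default.yaml`, loaded strictly: unknown keys are
errors). The bundled defaults are the published base case:

* utilities by NYHA class 0.72 / 0.72 / 0.53 / 0.47 (SDs 0.25 / 0.25 /
  0.32 / 0.35, Beta-sampled in PSA); stroke disutility 0.39 (no SD,
  fixed);
* adverse-event probabilities per arm (e.g. stroke 0.153 TAVI, 0.125
  SAVR), interpreted as cumulative over the five-year trial follow-up and
  converted to annual values under a constant hazard,
  $p_{\text{annual}} = 1-(1-p)^{1/5}$ (knob `event_annualization` can
  declare them already annual). The cited trial outcomes are five-year
  results, which motivates the default;
* entry distributions (TAVI 0.36/0.28/0.10/0.01 + death 0.25; SAVR
  0.34/0.30/0.07/0.02 + 0.27), each summing to one;
* unit costs in 2020 IRR, four of them Gamma-sampled (the two
  hospitalization and two reoperation items, the only ones printed with
  SDs).

Duplicate TIA rows in the published event table carry identical values and
collapse to a single entry; TIA itself is carried in the configuration but
drives neither a state nor a cost item under the default assignment.

**The cost-assignment table is data, not code.** Each cost item declares
where it accrues: `(arm, PROCEDURE)`, `(arm, ACUTE_EVENT, event)` weighted
by the event probability, or `(arm, PER_CYCLE_EVENT, event)` recurring.
The source evidence never states which arm bears the 800M IRR valve
prosthesis cost; charging it to SAVR's procedure phase alone would exceed
SAVR's entire published per-patient cost, so the default ties it (like
reoperation) to the aortic-valve reintervention probability. This is a
modelling choice exposed in the configuration, not buried in code.

**Long-term mortality** is the model's weakest-evidence input: nothing is
published beyond year one. The default (`CONSTANT_YEAR1`) holds the
first-year all-cause death probability constant for all later cycles --
the only zero-extra-data option -- and is deliberately prominent because
lifetime QALYs are highly sensitive to it. `annual_death_override`
(scalar or per-arm) and `USER_TABLE` (per-cycle vectors) replace it.

## Calibration to the published base case

Under the documented defaults the model produces TAVI 1.58 QALYs /
552M IRR and SAVR 1.47 / 108M -- the right ordering and plausible
magnitudes, but not the published 1.27 / 0.90 QALYs and 720M / 352M IRR,
because the two under-specified inputs above (post-year-1 mortality and
the valve-cost assignment) dominate the levels. The bundled
`model_calibrated.yaml` documents one knob setting that lands every
arm-level quantity within 15% of the published table:

* `annual_death_override: {TAVI: 0.3312, SAVR: 0.4912}` -- per-arm
  long-term death probabilities solved (by root finding on the model's
  QALY output) so each arm reproduces its published QALYs exactly;
* the valve-prosthesis cost moved to an acute event weighted by the
  new-atrial-fibrillation probability -- the only published event
  probability large enough to carry the cost difference.

With these two settings the model yields TAVI about 651M IRR / 1.270
QALYs, SAVR about 341M / 0.900, ICER about 838M IRR per QALY (the
acceptance script recomputes these at run time). The reconstruction is
not uniquely identified: other assignment/mortality combinations could
land in the same band, and the calibrated ICER remains some 16% below the
published 995M. We report the calibration as documentation of what the
published numbers imply, not as evidence about the underlying mapping.

## Uncertainty analysis

**PSA.** Only parameters printed with an SD are sampled: the four
utilities from moment-matched Beta distributions
($c = m(1-m)/s^2 - 1$, $\alpha = mc$, $\beta = (1-m)c$) and the four
Gamma-tagged costs (shape $(m/s)^2$, scale $s^2/m$) -- standard
method-of-moments practice where only a mean and SD are published.
Utilities are common parameters: one draw applies to both arms. Every
iteration reruns the full two-arm model. "Mean ICER" is ambiguous, so
`psa_summary()` always reports both the ratio of means (headline, by
default) and the mean of per-draw ratios over the north-east quadrant with
the excluded count.

**CEAC.** The probability of cost-effectiveness at WTP $\lambda$ is the
fraction of draws with $\lambda\,\Delta E - \Delta C > 0$; a draw with net
monetary benefit exactly zero counts as not cost-effective. The default
grid steps in quarter-GDP increments and contains the 1x and 3x anchors
exactly.

**One-way analysis.** The published range "5 to 150% changes" conflicts
with reported ICERs below the base value at the low end; we resolve it as
a multiplier grid 0.05x--2.50x (knob `owsa_grid`, fully configurable) and
report both grid ends. Event-rate multipliers apply to both arms
simultaneously and clip at 1 with a warning. The tornado ranks parameters
by ICER swing (max minus min), descending, alphabetical tie-break.

## The microsimulation oracle

`simulate_cohort()` is an independently coded patient-level simulator over
the identical state process: entry state from the entry distribution, one
uniform per cycle through the inverse CDF of the same transition rows,
rewards and discounting identical to the cohort engine. It exists to
validate the cohort algebra, and doubles as the package's synthetic-data
generator: its event logs have exactly the statistical structure the
cohort model assumes. Each patient owns a substream seeded from
`(master seed, patient id)`, so enlarging the cohort never perturbs
earlier patients.

What the generator deliberately does *not* emulate about real registries:
individual covariates (age, sex, frailty), inter-NYHA drift,
time-varying hazards, correlated costs, or informative censoring. Tests
passing against it therefore certify the *internal* consistency of the
cohort engine, not the external validity of the published parameters.

## Numerical choices and test scale

* Probability conservation is enforced to $10^{-9}$ on every trace row;
  transition rows sum to one exactly by construction.
* Moment round-trips are tested to $10^{-9}$ relative; sampled-moment
  recovery uses $10^6$ Beta draws (tolerance 0.001 on mean and SD).
* Cohort-vs-microsimulation agreement is asserted within 3 Monte-Carlo
  standard errors: at 200,000 patients per arm for the default
  configuration, and at 20,000 patients for five randomized
  configurations (the 3-SE bound is valid at any $n$; the smaller
  replicates keep the suite fast). Occupancy frequencies are checked at
  50,000 patients.
* The regular suite runs PSA determinism and directional checks at
  150--800 iterations; the acceptance script uses 4,000; 10,000 is the
  recommended production size.
* Degenerate configurations (single utility, constant hazard, no
  strokes) are checked against the geometric-series closed form
  $u\,s_0\sum_t (1-p)^{t-1}/(1+r)^t$ to $10^{-9}$.

## Currency display

IRR amounts are converted at the fixed 250,000 IRR/US$ 2020 average and
rounded half-up to whole dollars for display only. The published US$
renderings of the WTP thresholds are internally inconsistent (2,205 vs
2,206 for 1x GDP; 6,075 vs 6,618 for 3x); the package always computes
from the stated rate (2,206 and 6,617) and leaves the discrepancy to this
note.

## Known limitations

* No age-dependent background mortality or national life tables; the
  cohort is homogeneous.
* No tunnel states beyond the single stroke split; recurrent strokes are
  not distinguished.
* The lifetime extrapolation rests entirely on the long-term mortality
  knob; conclusions about absolute QALYs should be read as conditional on
  it.
* Exactly two strategies; no multi-way efficiency frontier.
* No expected-value-of-perfect-information analysis.
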