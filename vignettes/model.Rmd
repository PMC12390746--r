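---
title: "A decision-analytic model for response-predictive biomarkers in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model for response-predictive biomarkers in advanced NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1hta)
```

## The question the model answers

Advanced NSCLC patients without targetable mutations receive, depending on
tumour PD-L1 expression, immunochemotherapy (<1% and 1–49%) or
pembrolizumab monotherapy (≥50%). Only a minority respond durably. A
biomarker test that predicts response to immunotherapy could either *spare*
non-responding patients an expensive and toxic drug (low-expression strata)
or *intensify* treatment for predicted nonresponders (high-expression
stratum). `pdl1hta` implements an early-HTA decision model that prices
these hypothetical strategies before any such test exists: what do QALYs
and costs look like for a test with a given sensitivity and specificity,
and what is the headroom — the value of a perfect test?

## Structure and assumptions

### Decision tree

Response is binary: progression-free at 12 months. The reference responder
status differs by stratum — response to immunochemotherapy for <1% and
1–49% (prevalence `r_combo`), response to immunotherapy alone for ≥50%
(prevalence `r_mono`) — because that is the quantity each stratum's test is
asked to predict. Responders are *nested*: anyone who fails the stronger
(combination) arm also fails the weaker arm. This single assumption
identifies the whole 2×2 joint responder table from the two marginal rates,
and the package enforces it as a validation invariant. Its two corollaries
drive the results:

* a combination responder rerouted to chemotherapy by a false-negative test
  still responds with probability `r_mono / r_combo`
  (`response_given_comparator()`);
* an immunotherapy nonresponder given the combination is rescued with
  probability `1 - (1 - r_combo) / (1 - r_mono)`
  (`crossover_response_rate()`).

For the ≥50% stratum no trial compares the two arms directly, so the
combination response rate is derived from an indirect-comparison PFS hazard
ratio of 1.81. Two conversion conventions are implemented. The default,
risk scaling (`1 - (1 - r)/HR`), divides the nonresponse *risk* by the
hazard ratio; it is the arithmetic that reproduces the published derived
percentages (65.5%, 55.2%, 44.8%) exactly, which is why it is the default.
The proportional-hazards alternative (`r^(1/HR)`, `derivation_mode =
"HR_HAZARD_POWER"`) is available for exploration; it yields 58.2% instead
of 65.5% here, a reminder that indirect-comparison conversions are a real
source of structural uncertainty.

Published ratios are quoted at printed precision: 19.3/32.8 is printed as
58.7% although the printed inputs give 58.84%. The package always computes
from its inputs and never hard-codes the rounded quotient; tests accept the
printed value within half a printed-precision unit.

### Markov model

Five states — response-on-treatment, stable nonresponse, progression,
disease death, other-cause death — evolve in monthly cycles over a 60-cycle
(five-year) horizon. Sub-cohorts defined by the decision tree (regimen ×
responder status) evolve independently and are summed for reporting; death
states are absorbing, and every trace row conserves mass to 1e-10 by
construction (checked in the engine).

* **Responders** face a constant per-cycle progression probability from an
  exponential fit to the arm's PFS anchors (`fit_exponential()`: least
  squares of the cumulative hazard against time through the origin). By
  default the hazard applies from cycle 1 (`responder_pfs_mode =
  "from_cycle_1"`): the 12-month response definition is carried by the
  decision tree's responder status, while progression *timing* follows the
  fitted curve throughout. The alternative reading — responders are immune
  to progression during the 12-month response window — is implemented as
  `"after_12m"` and flagged here because the two give different responder
  life-years; the default was chosen because the fitted PFS curve is the
  only timing information available for the response state.
* **Nonresponders** either die or progress within the first 12 months. The
  split comes from the arm's 12-month PFS/OS gap (`nonresponder_split()`).
  The dying stream follows the exponential shape implied by the 12-month OS
  anchor, with its cumulative incidence rescaled so the stream is fully
  dead at cycle 12 (the conditional hazard at the boundary is 1). The
  within-year mortality shape behind the original analysis is not public,
  so the exponential shape is an assumption and the anchors are config
  inputs. The progressing stream stays in stable nonresponse and moves to
  progression *deterministically* at the start of the cycle after the mean
  time to progression (9 months). A point assumption is stated for this
  quantity, and the deterministic jump keeps the trace auditable; it also
  makes the progression inflow at month 10 exactly the stream mass, which
  the tests exploit.
* **Progression** carries a constant per-cycle death probability
  `1/mean_pps` (mean 5.4 months). A memoryless geometric sojourn is the
  only time-homogeneous Markov representation that matches the mean; a
  fixed countdown would need tunnel states and contradict the formalism
  used everywhere else.
* **Background mortality** `q_x` (scalar or per-cycle schedule) applies in
  every alive state. Within a cycle the disease event is evaluated first
  and other-cause death applies to the survivors, including patients who
  progressed that cycle. At monthly granularity with `q_x` of order 0.001
  the ordering effect is second order, but it is fixed and documented so
  the microsimulation can reproduce the engine exactly.

No half-cycle correction is applied: rewards accrue as occupancy × monthly
reward from cycle 1 to the horizon, with cycle 0 the decision-tree moment
carrying only the one-time costs. The model's outputs are *differences*
between two strategies run on identical cycles, in which the correction
largely cancels.

### Economics

QALYs: `(on-treatment occupancy × u_response + progression occupancy ×
u_progression − on-medication occupancy × aggregated disutility) / 12`,
discounted at 1.5%/year (health). The stable-nonresponse state uses the
response-state utility: those patients are on treatment and not yet
progressed, and no separate utility is published for them.

Costs, discounted at 4.0%/year: medication per cycle while on treatment
(until progression by default, or a fixed number of months), side-effect
management while on medication, state costs, one-time discontinuation cost
at the medication-stop event, terminal-care cost at death transitions, and
the tree-stage one-time costs (biopsy, PD-L1 determination, and the
biomarker test cost — zero by default — only under the biomarker strategy).

Two attachment choices deserve a note. Side-effect disutilities *and*
management costs are prevalence-weighted sums attached per cycle while on
medication; the costs are therefore specified in EUR per month of
treatment. This is the symmetric reading of "aggregated into the health
state" for both quantities; episodic one-off costs can be emulated by
dividing by an expected treatment duration. Terminal-care cost applies to
other-cause deaths as well as disease deaths by default (the stated rule is
"patients who died"); `economics.terminal_care_other_cause = FALSE`
switches it off.

ICERs use quadrant semantics: EUR per QALY gained (cost-effective when at
most the threshold) in the gained/extra-cost quadrant, EUR saved per QALY
lost (cost-effective when at least the threshold) in the lost/saving
quadrant, dominance without division, and a cost-minimisation verdict at
ΔQALY = 0. The threshold is €80,000 per QALY in both directions.

## Parameters

| Parameter | Units | Default | Source/why |
|---|---|---|---|
| `r_combo`, `r_mono` | probability | 0.328/0.193 (<1%), 0.429/0.177 (1–49%), HR-derived 0.655/0.375 (≥50%) | pooled trial rates, pinned by the generator |
| `hr` | — | 1.81 (≥50% only) | indirect comparison, PFS |
| `sensitivity`, `specificity` | probability | 1/1 | headroom default; scenarios 75/75, 90/60, 60/90, 0/0 |
| `test_cost` | EUR | 0 | the test is hypothetical |
| `mean_time_to_progression_nonresp` | months | 9 | expert-opinion point assumption |
| `mean_post_progression_survival` | months | 5.4 | literature mean; DSA 50–150% |
| `discount_rate_health`, `discount_rate_cost` | per year | 0.015 / 0.04 | national HTA guideline |
| `wtp_wta_threshold` | EUR/QALY | 80,000 | high disease burden |
| `horizon_cycles` | months | 60 | five-year horizon |
| `monthly_other_cause_death` | probability/cycle | sampled 0.0010–0.0020 | life-table order of magnitude for the age group |

## What the synthetic generator emulates

The original per-arm survival anchors, utilities, side-effect tables and
unit costs are in supplementary tables that are not publicly deposited.
`generate_parameter_set()` therefore samples them from plausible ranges,
documented here once and not tuned thereafter:

| Quantity | Range |
|---|---|
| `u_response` | 0.70–0.85 |
| `u_progression` | 0.50–min(0.70, `u_response` − 0.05) |
| immunotherapy-containing medication | €5,000–€9,000 per cycle (+ chemo cost for the combination) |
| chemotherapy medication | €500–€2,000 per cycle |
| side effects | 3–8 per regimen; prevalence 0.02–0.30, disutility 0.01–0.08, cost €20–€150/month |
| state costs | response €300–€700, progression €800–€1,500 per cycle |
| one-time costs | biopsy €600–€1,000, PD-L1 €100–€200, discontinuation €500–€1,500, terminal care €8,000–€15,000 |
| 12-month OS uplift among nonresponders | chemo 0.15–0.30; immunotherapy-containing 0.30–0.45 |
| PFS anchors | months 12/18/24 from the exponential through `pfs12`, log-noise SD 0.01 |

Each arm's `pfs12` equals its response rate — that is the response
definition, not a coincidence — and `os12 = pfs12 + uplift × (1 − pfs12)`.
The higher OS uplift on immunotherapy-containing arms encodes the stated
mechanism for the QALY loss in the low-expression strata: nonresponders
survive the first year longer on immunochemotherapy than on chemotherapy.
All draws come from one seeded generator (`withr::local_seed`), so a seed
pins the entire set byte-for-byte, and the seed is stored on the object.

What passing tests on synthetic sets do **not** show: agreement with the
original cost and QALY magnitudes (those depend on the non-public tables),
Dutch life-table age structure (background mortality is a flat monthly
rate unless a schedule is supplied), or any statement about a real
biomarker. They do show that the machinery — tree, engine, rewards,
comparisons — is internally correct and reproduces the published *derived
rates*, *incremental-delta arithmetic* and *qualitative sign pattern*
(cost-saving/QALY-losing with savings per QALY lost above the threshold in
the low-expression strata, including the Se = Sp = 0 corner;
QALY-gaining/cost-increasing and not cost-effective in the ≥50% stratum;
ICER reduction under equal therapy durations).

## Numerical choices and degenerate inputs

* Mass conservation is asserted at 1e-10 per trace row; initial
  distributions must sum to one within 1e-12.
* `r_combo = 0` is an undefined-rate error (the conditional ratio has no
  meaning); `r_mono = 1` leaves no nonresponders and makes the crossover
  rate undefined; `pfs12 = 1` is rejected when a nonresponder schedule is
  requested.
* The HR conversion clips to [0, 1] (an HR below `1 − r` would otherwise
  produce a negative rate).
* `h_die` rescaling divides by `1 − F(t−1)`; the final cycle's conditional
  probability is forced to exactly 1, and a zero-hazard OS anchor
  (`os12 = 1`) degenerates to the uniform shape — the stream then has mass
  zero anyway.
* The exponential fit requires strictly positive survivals; synthetic
  anchors are clamped to a running minimum so log-noise can never produce
  a rising curve.
* In the one-way DSA, lowering `u_response` below `u_progression` would
  violate the utility ordering; the DSA clamps `u_progression` down to
  `u_response` (a documented repair) rather than silently skipping the
  range.
* Fixed-duration medication stops charge the discontinuation cost at the
  fixed stop only; progression before the stop ends medication but the
  one-time cost is tied to the rule's stop event.

## Verification strategy and problem sizes

The cohort engine computes the exact expectation of a fully specified
individual-level stochastic process, so the package ships that process as
an independent microsimulation (`microsim_oracle()`): per-patient Bernoulli
draws through the same schedules with the same reward attachment, written
against the engine rather than from it. The test suite runs the comparison
at 100,000 patients for 20 generator seeds per stratum and requires
agreement within three standard errors for both QALYs and costs, alongside
a deterministic pathway (all probabilities 0 or 1) where the two must agree
to machine precision. Exponential-rate recovery is checked noiseless
(exact) and under log-noise (unbiased within three standard errors across
200 seeds). Decision-tree masses are checked against exhaustive enumeration
of the joint-status × test × routing outcomes on a parameter grid. These
sizes keep the default suite near a minute on one core while leaving
Monte-Carlo error well below the effects being tested.

## Known limitations

* No probabilistic sensitivity analysis: parameter uncertainty is explored
  one-way only, mirroring the analysis the model implements.
* Progression and death cannot be separated in the responders' PFS curves,
  so all post-response events are treated as progression followed by the
  5.4-month post-progression survival; other-cause death during that
  window is only captured through `q_x`.
* The five-state structure is the minimal set consistent with the described
  transitions; a finer published state chart might distinguish, e.g.,
  on/off-treatment progression.
* Currency is assumed pre-indexed (2021 EUR); no indexation machinery is
  included.
* Test turnaround time, tissue availability and other implementation
  factors are out of scope.
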