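# pdl1hta

Early health technology assessment (HTA) of biomarker tests that predict
response to immunotherapy in advanced non-small-cell lung cancer (NSCLC).

Immune checkpoint inhibitors (pembrolizumab) are a standard treatment for
advanced NSCLC, but durable response is limited to a minority of patients
while costs and side effects accrue for everyone. A predictive biomarker
that identifies likely responders could redirect treatment: in patients with
tumour PD-L1 expression <1% or 1–49% a negative test would *omit*
immunotherapy (chemotherapy alone instead of immunochemotherapy); in
patients with PD-L1 ≥50% a negative test would *add* chemotherapy to
immunotherapy. `pdl1hta` quantifies, before such a test exists, what a test
of given accuracy would be worth — the question asked in early HTA.

The package targets health-economics researchers and test developers who
want to explore minimal performance requirements and optimal positioning of
response-predictive biomarkers.

## Model

Each PD-L1 stratum (<1%, 1–49%, ≥50%) is analysed with a decision tree
feeding a monthly-cycle Markov cohort model over a five-year horizon:

* **Decision tree.** Response is binary, defined as progression-free
  survival (PFS) at 12 months. Responder prevalence per stratum comes from
  pooled trial data (32.8%/19.3% combination/chemo for <1%, 42.9%/17.7% for
  1–49%, 37.5% immunotherapy-alone for ≥50% with the combination rate
  derived from a PFS hazard ratio of 1.81 by risk scaling,
  `1 − (1 − r)/HR = 0.655`). Responders are nested: responders to the
  weaker arm are a subset of responders to the stronger arm, so a
  combination responder rerouted to chemotherapy responds with probability
  `r_mono / r_combo`, and an immunotherapy nonresponder given the
  combination is "rescued" with probability
  `1 − (1 − r_combo)/(1 − r_mono)`. A test with sensitivity Se and
  specificity Sp routes patients accordingly.
* **Markov model.** Five states: response-on-treatment, stable nonresponse,
  progression, disease death, other-cause death. Responders progress at the
  constant rate fitted (exponential, least squares on the log survival
  through the origin) to the arm's PFS anchors. Nonresponders either die or
  progress within the first 12 months, split by the arm's 12-month PFS/OS
  gap; the dying stream follows the OS-anchor exponential rescaled to
  complete by month 12, the progressing stream moves to progression at
  month 9. Post-progression survival is geometric with mean 5.4 months.
  Background mortality applies in every alive state.
* **Economics.** QALYs use state utilities minus prevalence-weighted
  side-effect disutilities while on medication, discounted at 1.5%/year;
  costs cover medication until progression (or a fixed duration), state
  costs, side-effect management, one-time biopsy/PD-L1/discontinuation/
  terminal-care costs, discounted at 4.0%/year. Strategies are compared by
  the ICER ΔC/ΔQ with quadrant semantics against a willingness-to-pay /
  willingness-to-accept threshold of €80,000 per QALY.

The exact trial-level input tables behind the original analysis are not
publicly deposited, so `generate_parameter_set()` creates seeded synthetic
parameter sets that pin the published anchor values and sample the rest from
documented plausible ranges; every number below therefore illustrates the
mechanics, not the original cost estimates. An individual-level
microsimulation (`microsim_oracle()`) independently cross-checks the cohort
engine.

## Worked example

```r
library(pdl1hta)

params <- generate_parameter_set("LT1", seed = 1)  # PD-L1 < 1%, synthetic inputs
headroom(params)                                   # perfect-test upper bound
#> <strategy_comparison>
#>   dQALY: -0.0244   dCost: EUR -27,809
#>   ICER: EUR 1,138,707 saved per QALY lost
#>   cost-effective at EUR 80,000 per QALY

scenario_table(params) |>
  dplyr::select(label, se, sp, delta_qaly, delta_cost, icer, cost_effective)
#>   label        se    sp delta_qaly delta_cost     icer cost_effective
#> 1 headroom   1     1       -0.0244    -27809. 1138707. TRUE
#> 2 se75_sp75  0.75  0.75    -0.0414    -26589.  641907. TRUE
#> 3 se90_sp60  0.9   0.6     -0.0239    -18978.  794232. TRUE
#> 4 se60_sp90  0.6   0.9     -0.0589    -34199.  580161. TRUE
#> 5 se0_sp0    0     0       -0.0924    -22927.  248076. TRUE
```

Withholding immunotherapy on a negative test loses a small amount of QALYs
(responders wrongly rerouted progress faster; nonresponders survive the
first year less long on chemotherapy) but saves far more than €80,000 per
QALY lost at every accuracy — even a useless test (Se = Sp = 0) — because
the savings are driven by the price of the immunotherapy itself. Accuracy
still matters: the savings per QALY lost are maximal for the perfect test.
In the ≥50% stratum (`generate_parameter_set("GE50", ...)`) the pattern
reverses: adding chemotherapy on a negative test gains QALYs at a large cost
increase and is not cost-effective at €80,000 per QALY gained unless both
arms share the same therapy duration
(`medication_duration_scenario()`). One-way sensitivity analyses
(`one_way_dsa()`) vary post-progression survival over 50–150% and the state
utilities up to 1.0.

See `vignette("model")` for the model's assumptions, parameters and design
choices.

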