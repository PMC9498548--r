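---
title: "Modelling CKD progression under healthcare disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CKD progression under healthcare disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdflow)
```

## The model and its assumptions

`ckdflow` simulates a closed state population moving down the chronic
kidney disease (CKD) stage ladder. The state variables are stocks:
`Population` (initialised to Tennessee's 2020 census count, 6,910,840),
`Stage1` … `Stage5`, `ESRD`, and the absorbing `Dialysis`, `Transplant`
and `Deaths`. All stocks except `Population` start at zero. There are no
births, deaths outside ESRD, or migration, so total population is
conserved exactly; that conservation is a standing regression test, not
an approximation.

Three mechanisms connect the stocks:

1. **Incidence.** People enter stage 1 at
   `Population · mean(r) / 100` per year, where `mean(r)` averages the
   four named risk-factor rates (diabetes, hypertension, dietary
   patterns, lifestyle patterns). The arithmetic mean is a deliberate
   neutral choice: the risk factors are named without a combination
   rule, and the mean keeps each factor's units and influence identical.

2. **Bias-driven progression.** The disparity level at stage *k* is the
   *additive* total `B_k` of four components — patient (non-adherence to
   self-care), primary care provider, nephrologist and healthcare
   system. "Cumulative" is read literally as a sum; the four components
   are interchangeable in their effect, and raising any one of them
   raises `B_k` linearly. `B_k` converts to the fraction of stage-*k*
   patients whose disease is unmonitored:

   `u_k = clamp(κ · B_k · (1 − c), 0, 1)`

   with gain `κ` (1/bias) and screening coverage `c` (the eGFR and
   serum-albumin testing channel, collapsed to a single fraction —
   per-stage eGFR thresholds are out of scope). Progression from stage
   *k* runs at `Stage_k · (ρ_k / 100) · [u_k + ρ_mon (1 − u_k)]`:
   unmonitored patients progress at the full base rate `ρ_k`, monitored
   patients at the fraction `ρ_mon` of it. The linear-in-bias,
   clamped form is the simplest function that is zero at zero bias,
   monotone, and saturates; it is isolated behind `total_bias()` and
   `unmonitored_fraction()` so alternatives can be swapped without
   touching the ladder.

3. **ESRD outflows.** ESRD empties into dialysis, transplant and death
   at percentage rates. The death outflow carries the same
   monitored/unmonitored factor as the progressions, so raising the
   ESRD-stage bias raises death incidence — the qualitative behaviour
   the scenario set expects of the final stage. Dialysis and transplant
   rates are unmodulated.

Cumulative counters (`ProgressionTo2` … `ProgressionToESRD`,
`DeathIncidence`) integrate each progression flow from zero. Endpoint
comparisons ("progression to stage 2 by 2022") read these counters, not
the instantaneous stage populations: a stage stock can shrink as people
move on, but total progression cannot, which matches endpoints quoted as
monotone accumulations from zero.

## Parameters

| Parameter | Unit | Default | Origin |
|---|---|---|---|
| `population_init` | persons | 6,910,840 | 2020 census, Tennessee |
| `diabetes_rate`, `hypertension_rate` | %/yr | 0.80 | base-run values |
| `diet_rate`, `lifestyle_rate` | %/yr | 0.80 | synthetic, set equal to the published risk rates |
| `provider_bias_stage1..5, esrd` | bias | 0.8, 0.08, 0.16, 0.073, 0.152, 0.33 | base-run values |
| `patient_bias_*` | bias | 0.10 | synthetic |
| `nephrologist_bias_*` | bias | 0.05 | synthetic |
| `system_bias_*` | bias | 0.10 | synthetic |
| `base_progression_rate_stage1..5` | %/yr | 8, 6, 4, 3, 2 | synthetic |
| `monitored_slowdown` (ρ_mon) | fraction | 0.25 | synthetic |
| `screening_coverage` | fraction | 0.30 | synthetic |
| `bias_gain` (κ) | 1/bias | 0.5 | synthetic |
| `dialysis_rate`, `transplant_rate`, `esrd_death_rate` | %/yr | 40, 15, 10 | synthetic |

The synthetic defaults are fixed by two requirements: every stage and every counter must show
nonzero flow by 2022 from a standing start, and the stage-1 total bias
(0.8 + 0.10 + 0.05 + 0.10 = 1.05) must sit well inside the unclamped
region of `u_k` so the documented bias step changes act linearly. They
are *not* calibrated to any observed CKD series, and absolute endpoint
magnitudes should be read as illustrative. The packaged scenarios
(`ckd_scenarios()`) encode the documented step changes: diabetes
0.80→1.15 with hypertension 0.80→1.25 ("current"), and the per-stage
provider-bias steps 0.8→1.3, 0.08→1.55, 0.16→1.32, 0.073→1.151,
0.152→0.275, 0.33→0.72. (For the stage-1 step, 1.3 from the narrative
was preferred over the 1.33 printed in the summary table.) Scenario
overrides are whole-run constants — the comparisons are between complete
base and altered runs, not mid-run switches.

## Numerical choices

* **Integration** is fixed-step explicit Euler, the classical system
  dynamics default; dt = 0.0625 year. First-order convergence is
  verified against the closed form of a linear decay stock (endpoint
  error halves when dt halves, and is under 1% at dt = 1/64 over 12
  years).
* **Percentage-rate units**: a parameter value *p* multiplying a stock
  means *p*/100 per year. Percentage-rate parameters are rounded to two
  decimal places once, when the model is built — not at every step.
  Bias components are dimensionless and not rounded (defaults such as
  0.073 carry three decimals).
* **Non-negativity**: if a stock's total outflow demand over a step
  exceeds its content, all its outflows are scaled proportionally so it
  lands exactly on zero. The scale factor uses the stock's content
  alone (inflows arriving in the same step are ignored), which is
  slightly conservative but keeps the limiter single-pass and exactly
  conservative. At the model's rate scales (≤ 55%/yr · dt = 1/16) the
  limiter never engages in practice.
* **Counters** are stocks fed by boundary flows that share the
  progression-rate auxiliary. Because a flow has one source and one
  sink, the counter inflow is not subject to the source stock's
  limiter; if a stage stock were ever floored, the counter could
  overcount that step. With the default rates this cannot occur, and
  the mass-balance check covers the state stocks exactly.
* **Auxiliary evaluation** follows a topological order of the
  auxiliary dependency graph (cycles are a validation error), with
  declaration order breaking ties, so runs are bitwise reproducible.
* **Cycle enumeration** is a rooted DFS visiting only nodes at least
  the root, so each simple cycle is found exactly once; cycles are
  canonicalised to the rotation starting at their smallest node
  (direction is preserved — reversal is a different cycle in a
  digraph) and sorted by length then node sequence. It is checked
  exhaustively against a permutation-over-subsets brute force on random
  digraphs of up to 8 nodes.
* **Calibration** is bisection on one scalar parameter, with
  monotonicity direction established at the bounds and infeasible
  targets rejected with the achievable interval. Only continuous
  parameters calibrate to fine tolerances: percentage-rate parameters
  are quantised to 0.01 by the rounding rule, so sub-0.01 recovery is
  only meaningful for bias-unit parameters.

## The causal-loop fixture

The social-determinants diagram ships with ten labelled loops: six
reinforcing (economic deprivation R1–R3, morbidity/mortality R4–R5,
access to care R6) and four balancing (sick leave B1, food access B2,
housing/toxins B3, public assistance B4). The individual arrow signs are
a reconstruction: each loop narrative is encoded as an explicit signed
cycle realising its published polarity, with shared edges
sign-consistent. In particular, poverty↔health feedback appears both
reinforcing (R6, direct) and balancing (B2/B4); the balancing versions
close through a corrective `PublicAssistance` link, and that closure is
the fixture's reconstruction, not a printed arrow. Channels tag each
edge as a disparity influence (red) or a general social influence
(blue).

## What the tests do and do not show

The test suite and acceptance script exercise the model under its own
synthetic defaults: conservation, counter monotonicity, the
qualitative bias findings (raising any bias component of any stage
weakly raises its downstream cumulative progression at every time
point, on a 5-point grid per component), scenario direction for each
packaged step change, and recovery of known bias rates from simulated
endpoints (20 random draws, recovered within 10⁻³). Problem sizes:
192-step runs over 2010–2022 for all model checks, 768 steps for the
integrator oracle, 200 random digraphs for enumeration equivalence.
Passing these shows the machinery is correct and internally consistent;
it does **not** validate the synthetic rates against real CKD
surveillance data, and no real-data inference should be drawn from the
absolute endpoint values.

## Known limitations

* Minority populations are aggregated into a single population stock;
  no stratification by subgroup, age or sex.
* No CKD regression to earlier stages, no cost modelling, no
  stochasticity and no Monte-Carlo uncertainty quantification.
* The expression language is plain arithmetic; there are no
  delay/smooth/lookup builtins.
* XMILE export is one-way (no import), and the exporter targets
  structural interchange, not execution-identical Vensim behaviour.
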