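---
title: "Non-adherence tree analysis: model, simulator design and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-adherence tree analysis: model, simulator design and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natar)
```

## The model

A non-adherence tree (NAT) transplants fault tree analysis from engineering
reliability into medication adherence. The *top event* is discontinuation:
a patient failing to complete the prescribed regimen. *Basic events* are
non-adherence factors (NAFs) — side effects, forgetfulness, supply
failure — each a binary outcome. Boolean gates connect them: **OR** (any
child suffices), **AND** (all children required), and **Priority-AND**
(**PAND**: all children, in the listed order). In the bundled case study
the intermediate layer is the five WHO adherence dimensions
(social/economic, patient-, condition-, healthcare- and therapy-related),
each an OR over its factors, with one AND pair: the ICT and manual
medicine-delivery subsystems, which must both be down to interrupt supply.

Three views of the same tree are provided, and they are deliberately
redundant so each can check the others:

1. **Qualitative** — `minimal_cut_sets()` expands the tree symbolically
   (OR concatenates child cut-set lists, AND/PAND forms pairwise unions)
   and minimises under the absorption law. Singleton cut sets are single
   points of failure. `evaluate_truth()` is the independent truth-table
   oracle: the test suite checks the cut-set disjunction against it on
   every assignment of the case-study tree (2^12) and on randomly
   generated trees.
2. **Analytic** — `analytic_top_probability()` evaluates constant-hazard
   trees bottom-up: leaves via `1 - exp(-r d)`, OR/AND via the
   independent-combination rules, PAND via the ordered-exponential closed
   form (below). Exact for trees without shared events.
3. **Monte Carlo** — `simulate_cohort()` handles everything the closed
   forms cannot: decaying and age-stratified hazards, repairable
   subsystems, trajectories, attribution and interventions.

Independence of factors is assumed throughout, as is standard in fault
tree practice when no dependency data exist; it is the strongest modelling
assumption in the package and is restated in the API documentation.

## Rate estimation

For a factor observed in study *i* (participants $NoP_i$, regimen length
$DoM_i$ days, $c_i$ discontinuations attributed to the factor):

$$NARS_i = c_i / NoP_i, \qquad NAR_i = NARS_i / DoM_i, \qquad
WNAR = \sum_i NAR_i \frac{NoP_i}{GrandNoP},\quad
GrandNoP = \sum_i NoP_i .$$

Two conventions matter and were genuinely open:

* **GrandNoP sums participants, not non-adherent counts, and sums them
  over every pooled study** — including studies that never observed the
  factor. A factor seen only in one small study is thereby pooled toward a
  small rate rather than keeping its single-study rate, which is the
  behaviour a meta-analyst would want from a sample-size weighting. With
  the bundled six studies this gives $GrandNoP = 1450$.
* **Absent counts are "not observed", not zero.** An unobserved factor in
  a study contributes nothing to the numerator but the study's $NoP$
  still enters the denominator; asking for the NARS of an unobserved
  factor is an error rather than 0, because the study design simply did
  not measure it.

Printed-value comparisons in the tests use 4-significant-figure rounding,
matching how such tables are conventionally reported.

## Closed-form probabilities

An exponential factor with hazard $r$ per day occurs within $d$ days with
probability $1 - e^{-rd}$. Independent OR and AND combinations are
$1-\prod(1-P_i)$ and $\prod P_i$. For a PAND over exponential events with
hazards $\lambda_1..\lambda_n$ (indexed from the *last* event in the
required order), with partial sums $a_0 = 0$,
$a_m = -\sum_{j\le m}\lambda_j$:

$$P = \prod_i \lambda_i \sum_{k=0}^{n}
      \frac{e^{a_k t}}{\prod_{j \ne k}(a_k - a_j)} .$$

`p_pand_exponential()` takes rates in occurrence order and reverses
internally. Because the partial sums of strictly positive hazards are
strictly decreasing, the denominator differences cannot vanish for valid
input; the degeneracy guard (raise an error suggesting a small rate
perturbation) is defensive. Two independent checks are in the tests: a
sampling oracle that draws the event times directly (1e6 draws for the
acceptance property), and the partition identity that the six orderings of
three events sum to the AND probability. A numerical guard rejects any
result outside $[0,1]$ beyond 1e-9 and clamps inside it.

## Leaf rate models

| form | parameters (units) | default use |
|---|---|---|
| `constant` | `rate` (/day) | pooled WNARs |
| `linear_decay` | `initial_rate` (/day), `decay_fraction_per_day` | factors that fade, e.g. a care team's initial lack of adherence knowledge (1.5e-4/day losing 8% of the initial value per day) |
| `repairable` | `failure_rate` (/day), `mean_repair_time` (hours) | supply subsystems (8.12e-5 & 5.34e-5 /day; 4 h & 2 h repair) |
| `age_stratified` | band `rate`s (/day) + cohort `weight`s | social support: 4.138e-4 (<25), 1.379e-4 (25–45), 2.069e-4 (>45) |

Two ambiguities were resolved here as package design choices:

* **Decay day index.** "Rate on elapsed day $d$" uses *whole* elapsed days
  counted from 0, so the first dosing day uses the undecayed rate:
  `effective_rate(model, day)` floors `day`. This makes day semantics
  identical between the analytic helper and the simulator's per-day rate
  refresh, and the floor preserves monotonicity.
* **Cohort age mix.** No age distribution is published for the case-study
  cohort, so the age-stratified default weights are equal thirds; they
  are an explicit, overridable field of the rate model rather than a
  hidden constant.

## Simulator design

One Bernoulli trajectory is simulated per patient ("1000 iterations per
time-step" in the source material is read as 1000 participants, since it
equates iterations with participant behaviour); replicate cohorts under
consecutive seeds provide tolerance bands.

* **Step semantics.** Time advances in steps of `timestep` hours (default
  1; must divide 24). An active non-repairable leaf fires in a step with
  probability $1-e^{-r(d)\,\Delta t}$, $\Delta t$ in days. Because these
  per-step survival factors telescope, the marginal occurrence time is
  *exactly* exponential whatever the step size — the constant-rate
  simulator is unbiased against the closed form, and step-size robustness
  is a tested property rather than a hope.
* **Absorbing discontinuation.** Missing one pill makes the patient
  non-adherent; the first step in which the top event evaluates true
  (over the patient's cumulative occurrences) absorbs the patient and no
  further events are sampled. One consequence: the 2-day resupply delay
  attached to the limited-tablets factor affects only event timing
  semantics, never final counts, and is therefore recorded as label
  metadata only.
* **Repairable subsystems.** Each repairable leaf is a *system-level*
  alternating renewal process: exponential time to failure, fixed repair
  duration. A patient's dose is missed through this pathway only if the
  relevant subsystems are down at that patient's dosing step, which is
  assigned uniformly at random within each day. The published material
  states only rates and repair delays; checking availability at the
  dosing instant is the natural reading of a once-daily regimen.
* **Attribution and ties.** A discontinuation is attributed to the leaf
  that fired in the triggering step; if several fired in the same step
  the tie is broken uniformly at random (an $O(\Delta t)$ event).
  `contributions()` reports factor shares and their rollup to the
  top-level dimensions.
* **Common random numbers.** All firing uniforms are pre-drawn as a fixed
  `(patient, leaf, step)` array before the step loop. Under the same
  seed, scaling a hazard downward can only shrink the fired-event set, so
  an intervention scenario (`apply_improvement()`) is monotone
  *run by run*, not just in expectation — the paired baseline/improved
  delta is negative in every replicate by construction.

## The synthetic-study generator

`generate_synthetic_studies()` draws per-factor counts as
$\mathrm{Binomial}(NoP,\ 1-e^{-r\,DoM})$ — the same generative model the
estimators assume, with the exponential (not linear) rate-to-proportion
map for consistency with the probability model; at the hazard magnitudes
of real adherence data the two differ by under 1%. It emulates
sample-size and regimen-length heterogeneity across studies, and supports
the parameter-recovery tests (WNAR from a 1e5-participant synthetic study
recovers the generating rate within Monte Carlo error). It does **not**
emulate between-study rate heterogeneity, correlated factors,
under-reporting, or attrition — so passing recovery tests show estimator
correctness under the model's own assumptions, not robustness to real
studies that violate them.

## Problem sizes and numerical choices

The bundled case study is simulated at 1000 patients × 10 days × hourly
steps, the cohort size and regimen the case study defines. Stochastic
summaries in the test suite and acceptance script pool 30 replicate
cohorts: with ~225 discontinuations per cohort this puts the standard
error of a contribution share near half a percentage point and of the
mean probability near 0.002, comfortably inside the tolerances the
published values are compared at. Property tests use smaller cohorts
(hundreds to a few thousand patients) with 3-standard-error bounds.
Cut-set expansion is exact symbolic with a 2^20-product guard — fault
trees in this domain are small, and exactness keeps the truth-table
equivalence property unconditional. JSON/YAML output is written at full
precision (12+ significant digits); display rounding is left to
consumers.

## Known limitations

* Independence between factors; no common-cause groups.
* No shared (repeated) basic events across branches, and no spare gates.
* Enrolment is synchronous: all patients start on day 0, whereas real
  trials stagger starts.
* Within-day dose timing (timing/consistency adherence) is not modelled;
  only persistence is.
* The analytic path covers constant hazards only; everything else goes
  through the simulator.
* Published cumulative trajectory values for intermediate days of the
  case study depend on unstated internals of the original modelling tool;
  the tests hold them to order-of-magnitude sanity only, while end-of-
  regimen summaries are held to their published tolerances.
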