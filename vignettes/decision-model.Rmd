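---
title: "A calibrated six-state Markov model for upstream thromboembolic risk detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A calibrated six-state Markov model for upstream thromboembolic risk detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model: the structure and
assumptions, the parameters that matter and their defaults, what is
calibrated versus assumed, the numerical choices, and what the synthetic
cohort and the passing tests do — and do not — establish about real data.

## The decision problem

Older adults at high predicted risk of atrial fibrillation (AF) carry
substantial thromboembolic risk *before* AF is ever documented, and AF-led
prevention therefore intervenes late, particularly in women, whose strokes
are more severe and more disabling. The modelled intervention identifies the
top predicted-AF-risk quartile from routine primary-care records, screens it
with a photoplethysmography device, and offers individualized
anticoagulation to those at high thromboembolic risk. The comparator is
usual care: opportunistic AF detection and score-guided anticoagulation.

## Model structure

A cohort state-transition model with annual cycles and six mutually
exclusive states:

1. high risk without AF,
2. pre-AF substrate (subclinical atrial cardiomyopathy),
3. detected AF,
4. post-MACE,
5. disability and dependency,
6. death (absorbing).

Per cycle an individual can progress to the substrate state, have AF
detected, experience a MACE (myocardial infarction, stroke, systemic
embolism or cardiovascular death), enter long-term disability from the
post-MACE state, or die. The horizon runs from the cohort mean entry age
(84.66 years) to age 95 — eleven cycles — or until the death state holds
essentially the whole cohort.

Outgoing intensities are held as rates per 1000 person-years and converted
per cycle by the constant-hazard formula `p = 1 − exp(−λ·Δt)`; competing
exits from a state share the joint exit probability in proportion to their
intensities, so every generated matrix is row-stochastic by construction
(tested to 1e-12) with the death row a unit vector. Event counts are
accumulated from transition *fluxes*, never from occupancy differences.

Structural assumptions: the intervention's relative effect is constant over
cycles; adherence to anticoagulation is equal across arms once initiated;
anticoagulation-related major bleeding is not modelled explicitly (it enters
only through the net clinical event rates the model is calibrated to).

## What is observed, what is calibrated

The published evidence base supplies (a) baseline cohort marginals, (b)
sex-specific incidence rates per 1000 person-years for the top risk
quartile — AF onset 9.33 (men) / 7.24 (women), all-cause death 25.24 /
29.27, and others — and (c) lifetime event totals per 1000 under each
strategy (e.g. usual care, overall: 190 MACE, 78 ischaemic strokes, 36
severe-disability entries, 42 cardiovascular deaths). The per-cycle
transition probabilities themselves are *not* published; they were derived
from a regional cohort and calibrated.

The package makes that calibration explicit. AF onset and background
mortality are seeded directly from the observed rates. Four free channels
are fitted per sex to the four lifetime targets:

* a MACE intensity multiplier (base intensity seeded from the observed
  stroke + ischaemic-heart-disease rates);
* a post-MACE → disability intensity multiplier (base 100 per 1000 py);
* the stroke share of MACE events (an accounting split);
* the cardiovascular share of deaths from the post-event states (an
  accounting split).

Because the two shares have no effect on the state dynamics, they are
profiled out exactly at every objective evaluation (share = target/flux,
capped at its bound), and the remaining two multipliers are found by
Nelder–Mead on the log scale from three fixed starting points — a
deterministic search on a 2-D surface that typically converges to residuals
far below the declared tolerance of 0.5 events per 1000. A calibration that
cannot reach that tolerance raises an error carrying its best residuals.

Two structural mortality elevations give the cardiovascular-death channel
room to reach its target: background mortality is multiplied by 3 in the
post-MACE state and 5 in disability. These are design values in the range
reported for post-stroke and dependent populations; with the published
male targets (45 CV deaths against a lower male background mortality) the
milder 2/3 elevations leave the CV-death share pinned at its cap of 1, so
the steeper defaults were adopted as part of the model design.

The pre-AF substrate state is quantified nowhere in the evidence base: its
entry prevalence defaults to 0.15, its onward AF and MACE intensities are
doubled relative to the high-risk state, and both choices are exposed in
configuration and swept in sensitivity analysis.

## The intervention arm

The default parameterization is *reduced form*: the same base model is
calibrated to the intervention's lifetime column (under its AF-detection
hazard ratio, default 1.5), and the per-channel ratio of fitted multipliers
becomes the arm's constant hazard ratio — e.g. the fitted MACE hazard ratio
for women is about 0.61. Running the usual-care model under the fitted arm
reproduces the intervention targets, and the fitted arm strictly dominates
usual care on strokes, MACE and disability in both sexes.

A *mechanistic* cascade (quartile selection × screening sensitivity ×
anticoagulation uptake × anticoagulant stroke hazard ratio, composed onto
the stroke share of the MACE channel) exists for sensitivity analysis on
screening performance; with sensitivity 0 it collapses to usual care
exactly.

Outcomes are pooled at 52% women / 48% men — the stated composition of the
modelled cohort — while cohort synthesis uses the baseline table's
56.27%/43.72% split; the two differ in the source material and both are
configurable.

## Economics

Aggregate per-1000 cost components per arm are published (payer: screening
and diagnostics, anticoagulation, acute stroke care, long-term disability
care, non-stroke MACE hospitalisations; societal: informal caregiving,
long-term social care, productivity losses under age 75, nursing homes),
but unit costs are not. Each component is allocated to a driver — an event
flux (strokes, non-stroke MACE) or a state occupancy (alive person-years,
detected-AF person-years, disability person-years, under-75 person-years) —
and the unit cost is solved linearly so the calibrated trace reproduces the
published aggregate exactly. This turns every printed cell into a check on
the accounting machinery rather than an input to trust. The per-sex tables
print only totals; the overall component mix is scaled proportionally per
arm to match them.

Costs and QALYs are discounted at 3% per year, `x/(1+r)^t` with t the
zero-based cycle index. The half-cycle correction applies to
occupancy-based accumulations (state costs, QALYs), not to event fluxes.
Productivity losses attach to the under-75 share of survivors, computed
from the entry-age distribution shifted by elapsed cycles (differential
mortality by age is not tracked within the cohort recursion).

Utilities are not published. The defaults — 0.80 (high risk and substrate),
0.75 (detected AF), 0.65 (post-MACE), 0.40 (disability), 0 (death) — are a
plausible ordering, clearly flagged as package choices. Absolute QALY
increments therefore depend on this set and are checked only for sign and
ordering (women > men > 0, which the defaults reproduce: +83 / +55 per
1000); the published +74/+78/+69 are treated as reference values, not
reproduction targets.

## Uncertainty analysis

The probabilistic sensitivity analysis samples, per draw: state utilities
(beta), one multiplicative unit-cost factor per component shared across
arms (gamma, mean 1), the intervention arm's channel hazard ratios and the
baseline MACE multiplier (log-normal, mean 1), and the substrate prevalence
(beta). All distributions are moment-matched; zero dispersion degenerates
to a point mass, and a fully degenerate configuration reproduces the base
case exactly — a tested identity. Draws are independent; draws producing an
invalid model are rejected and logged, not resampled, so the retained set
remains an unbiased sample conditional on validity.

No dispersion magnitudes are published. The defaults (CV 15% for costs,
10% for utilities, 20% for hazard-ratio-type parameters) are conventional;
the resulting acceptability probabilities are *reported, not asserted*,
because they move with these choices. Under the defaults the model is
dominant in well over half of draws, consistent in direction with the
published probabilistic results (0.88 cost-effective at €30,000/QALY, 0.73
cost-saving), whose exact values cannot be reproduced without the original
dispersions.

The one-way tornado varies the published drivers — acute stroke unit cost
(±25%), substrate prevalence (0.05–0.30), screening sensitivity and
specificity (0.70–0.95), disability rates (±25%) — one at a time,
reporting net monetary benefit at €30,000/QALY and dominance status per
bound. Specificity enters through the confirmatory-workload scaling of the
intervention's screening costs (positive-test share sens·π + (1−spec)(1−π)
with π = 0.177, the incident-AF fraction).

## Population impact and budget impact

The population-impact computation partitions the cohort into three strata —
very high risk (pre-AF substrate, CHA₂DS₂-VA ≥ 4, or prior stroke), high
risk (score 3 by default; the boundary is not fixed in the source material
and is configurable), and moderate-to-high risk — and reruns both arms per
stratum and sex with the stratum's baseline-risk multiplier (1.6 / 1.0 /
0.6 before normalisation) applied to the AF and MACE intensities,
normalised so the share-weighted mean is 1 and the pooled calibration is
preserved. Per-capita impact is strictly ordered across strata and stratum
totals recover the pooled result to within about 0.2 events per 1000 (the
small gap is the concavity of cumulative incidence in the hazard scale).
One caveat: in this very elderly, multimorbid cohort the generated
*very-high* stratum holds roughly three quarters of the population, so —
unlike younger screening populations — the top stratum carries most of the
total value as well as the highest per-capita impact.

Budget impact truncates both arms' per-cycle cost streams at a 3–5-year
horizon, undiscounted by convention (a discounting toggle exists), with a
yearly uptake schedule (default: full uptake from year 1). Under the fitted
base case the avoided acute and long-term care costs exceed the additional
screening and anticoagulation spend in every year.

## The synthetic cohort

`generate_cohort()` draws sex (Bernoulli), age (normal truncated to
[65, 95]), twelve binary conditions (independent Bernoulli given sex, since
only marginal prevalences are published), CHA₂DS₂-VA (round-half-up
discretised sex-specific normal clipped to 0–9) and the substrate flag.
Because the upper age bound lies only ~1.5 SD above the printed mean, naive
truncation of N(84.66, 6.76) would bias the realised mean down by ~0.5
years; the generator instead solves for the location parameter whose
*truncated* mean equals the printed one. The score is drawn from its own
marginal rather than recomputed from the condition flags; a soft diagnostic
warns if gross contradictions (age ≥ 75 plus a scored comorbidity but score
< 2) exceed 5% of the cohort.

What the generator does *not* emulate: comorbidity correlations (real
multimorbidity clusters), the right-skew of the true age distribution,
age-dependent prevalences, and any dependence between the score and the
flags beyond their shared sex stratification. Tests that pass on this
cohort therefore establish that the pipeline reproduces the published
*marginals* under the stated sampling model — not that it would reproduce
joint structure in real records.

## Numerical choices and problem sizes

Tolerances: row-stochasticity 1e-12; occupancy conservation 1e-10;
calibration convergence 0.5 events per 1000 (achieved residuals are
typically < 1e-6); rate/probability round trip 1e-12 relative. Ties in
calibration multi-start are broken by lowest objective, then lexicographic
multiplier order. Degenerate inputs are handled explicitly: zero rates give
identity matrices and frozen cohorts; zero-dispersion PSA reproduces the
base case; empty strata are reported with a warning and zero totals.

The test suite runs the full per-sex calibrations, a 200,000-replicate
individual-level microsimulation as the oracle for the cohort recursion,
and PSA sets of 60–400 draws; the analysis scripts default to 2000 draws
(the `psa_config()` default is 10,000). The printed men/women incidence
ratios are reproduced from raw counts for *every* event row once one
observes that the published column truncates (rather than rounds) to two
decimals — the AF row, which prints no counts, matches as a truncated rate
ratio.

## Known limitations

Flat (non-aging) background mortality by default — lifetime calibration
absorbs age effects, and a Gompertz slope is available but off; one mean
entry age rather than an age distribution inside the Markov recursion;
no anticoagulation-related bleeding; independent PSA sampling (no
correlations, as none are published); per-sex cost components derived by
proportional scaling of the overall mix; and utilities chosen, not sourced.
The model reproduces the published cells it is calibrated to — that is its
design — so agreement with those cells validates the machinery, not the
external realism of the projections.
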