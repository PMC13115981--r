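# afcea

Decision-analytic cost-effectiveness modelling of an AI-guided strategy for
**upstream thromboembolic risk detection** in adults aged ≥65 at high risk of
atrial fibrillation (AF), compared with usual care (opportunistic AF
detection and score-guided anticoagulation).

AF-related strokes are frequent, severe and disabling in this population —
disproportionately so in older women — and a substantial share of
thromboembolic events occurs *before* AF is ever diagnosed. The package
implements the full evaluation pipeline for a strategy that uses an
EHR-based risk model to select the top predicted-AF-risk quartile, screens
it with a photoplethysmography device, and anticoagulates individuals at
high thromboembolic risk:

* a **six-state annual-cycle cohort Markov model** — high risk without AF,
  pre-AF substrate, detected AF, post-MACE, disability/dependency, death
  (absorbing) — run to age 95;
* **calibration** of the transition intensities to lifetime event targets
  (MACE, ischaemic strokes, severe-disability entries, cardiovascular
  deaths per 1000), separately per sex and strategy arm;
* **cost-effectiveness analysis** from the healthcare-payer and societal
  perspectives: discounted (3%/year) costs and QALYs, ICER/dominance, net
  monetary benefit;
* **probabilistic sensitivity analysis** (beta/gamma/log-normal parameter
  uncertainty, CEAC, probability of cost-saving) and a one-way
  deterministic tornado;
* **population-impact stratification** (events avoided, QALYs gained and
  savings per risk stratum) and a 3–5-year **budget impact** projection;
* a **synthetic cohort generator** reproducing the published baseline
  marginals (9677 individuals aged 65–95, 56.27% women, sex-specific
  comorbidity prevalences and CHA₂DS₂-VA distributions).

The model core is standard health-economic notation: per-cycle transition
probabilities derive from per-1000-person-year intensities by
`p = 1 − exp(−λ·Δt)` with competing risks resolved proportionally;
lifetime outcomes are transition fluxes accumulated over cycles; costs and
QALYs are discounted at rate r as `x/(1+r)^t` with a half-cycle correction
on occupancy-based quantities; `NMB(λ) = λ·ΔQALY − ΔCost`.

## Worked example

```r
library(afcea)
bc <- run_base_case()          # calibrate both arms per sex, run, cost out
clinical_outcomes_table(bc)
ce_summary_table(bc)
```

The calibrated lifetime outcomes per 1000 high-risk individuals (pooled at
52% women / 48% men):

```
   population    outcome usual_care intervention abs_difference rel_reduction
      overall       mace     191.08       126.24         -64.84        -34%
      overall    strokes      78.48        52.72         -25.76        -33%
      overall disability      36.32        26.20         -10.12        -28%
      overall  cv_deaths      42.40        29.96         -12.44        -29%
```

i.e. roughly 78 ischaemic strokes per 1000 under usual care, 26 of them
prevented by the AI-guided arm. The incremental economics:

```
  population d_cost_payer d_cost_societal  d_qalys     icer
     overall     -1278000        -1135000 69.7      Dominant
       women     -1400000        -1400000 83.2      Dominant
         men     -1000000        -1000000 55.0      Dominant
```

The intervention saves €1.278M per 1000 from the payer perspective (a
further €1.135M societally) while gaining QALYs — a dominant strategy, with
the largest savings and QALY gains in women. The numbered scripts under
`analysis/` run the full sequence (cohort synthesis, calibration,
economics, PSA/DSA, population impact and budget impact) and write their
tables under `results/`.

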