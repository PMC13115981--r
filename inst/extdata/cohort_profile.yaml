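# Baseline profile of the simulated high-AF-risk cohort (model entry),
# marginal statistics by sex. Counts: 4231 men, 5446 women, 9677 total.
n_total: 9677
p_female: 0.5627
age:
  mean: 84.66
  sd: 6.76
  min: 65
  max: 95
# Hypothesised atrial-cardiomyopathy ("pre-AF substrate") prevalence at entry.
# Not an observed marginal; default assumption, swept in one-way DSA.
pre_af_substrate_prevalence: 0.15
cha2ds2va:
  male:   {mean: 4.10, sd: 0.97}
  female: {mean: 3.84, sd: 0.88}
charlson:
  male:   {mean: 2.54, sd: 1.5}
  female: {mean: 1.96, sd: 1.3}
prevalence:
  heart_failure:                 {male: 0.292, female: 0.260}
  hypertension:                  {male: 0.876, female: 0.903}
  diabetes:                      {male: 0.534, female: 0.443}
  stroke_tia_se:                 {male: 0.108, female: 0.091}
  peripheral_vascular_disease:   {male: 0.242, female: 0.114}
  ischemic_heart_disease:        {male: 0.260, female: 0.131}
  dementia_cognitive_impairment: {male: 0.146, female: 0.215}
  chronic_kidney_disease:        {male: 0.347, female: 0.345}
  osahs:                         {male: 0.065, female: 0.029}
  dyslipidaemia:                 {male: 0.491, female: 0.570}
  anticoagulation:               {male: 0.187, female: 0.142}
  antiplatelet:                  {male: 0.260, female: 0.198}
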