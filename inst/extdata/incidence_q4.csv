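event,sex,subgroup,n_at_risk,events,rate,ci_low,ci_high,printed_ratio
af,male,q4_high_af_risk,3151,NA,9.33,8.72,9.98,1.28
af,female,q4_high_af_risk,4249,NA,7.24,6.77,7.75,1.28
stroke_tia,male,q4_high_af_risk,3151,310,4.27,3.81,4.77,1.18
stroke_tia,female,q4_high_af_risk,4249,352,3.60,3.23,3.99,1.18
heart_failure,male,q4_high_af_risk,3151,708,9.75,9.05,10.50,1.08
heart_failure,female,q4_high_af_risk,4249,882,8.40,7.83,8.99,1.08
ihd,male,q4_high_af_risk,3151,816,11.24,10.48,12.04,2.05
ihd,female,q4_high_af_risk,4249,536,5.48,5.02,5.96,2.05
pad,male,q4_high_af_risk,3151,753,10.37,9.65,11.14,2.16
pad,female,q4_high_af_risk,4249,470,4.80,4.38,5.26,2.16
cognitive_impairment,male,q4_high_af_risk,3151,440,6.06,5.51,6.66,0.65
cognitive_impairment,female,q4_high_af_risk,4249,904,9.24,8.64,9.86,0.65
ckd,male,q4_high_af_risk,3151,1042,14.36,13.50,15.26,0.99
ckd,female,q4_high_af_risk,4249,1406,14.37,13.62,15.14,0.99
death_all_cause,male,q4_high_af_risk,3151,1832,25.24,24.10,26.46,0.86
death_all_cause,female,q4_high_af_risk,4249,2865,29.27,28.21,30.37,0.86
stroke_tia,male,new_af,863,133,6.70,5.60,7.93,1.04
stroke_tia,female,new_af,851,125,6.37,5.31,7.60,1.04
heart_failure,male,new_af,863,476,23.94,21.84,26.20,1.06
heart_failure,female,new_af,851,442,22.54,20.50,24.74,1.06
ihd,male,new_af,863,235,11.82,10.36,13.43,1.64
ihd,female,new_af,851,141,7.20,6.05,8.48,1.64
pad,male,new_af,863,216,10.87,9.46,12.41,1.74
pad,female,new_af,851,122,6.22,5.17,7.43,1.74
cognitive_impairment,male,new_af,863,136,6.84,5.74,8.09,0.87
cognitive_impairment,female,new_af,851,154,7.85,6.66,9.20,0.87
ckd,male,new_af,863,359,18.06,16.24,20.03,0.64
ckd,female,new_af,851,553,28.20,25.90,30.65,0.64
death_all_cause,male,new_af,863,585,29.43,27.09,31.91,1.02
death_all_cause,female,new_af,851,563,28.71,26.40,31.18,1.02
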