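population,component,usual_care,intervention
all,informal_caregiving,890000,545000
all,longterm_social_care,1240000,780000
all,productivity_under75,210000,140000
all,nursing_home,650000,390000
women,total,3150000,1750000
men,total,2780000,1780000
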