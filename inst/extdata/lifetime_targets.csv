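population,outcome,usual_care,intervention,abs_difference,rel_reduction
overall,mace,190,125,-65,-0.34
overall,strokes,78,52,-26,-0.33
overall,disability,36,26,-10,-0.28
overall,cv_deaths,42,30,-12,-0.29
overall,qaly_increment,NA,74,NA,NA
women,mace,205,132,-73,-0.36
women,strokes,90,58,-32,-0.36
women,disability,44,31,-13,-0.30
women,cv_deaths,40,29,-11,-0.28
women,qaly_increment,NA,78,NA,NA
men,mace,176,120,-56,-0.32
men,strokes,66,47,-19,-0.29
men,disability,28,21,-7,-0.25
men,cv_deaths,45,31,-14,-0.31
men,qaly_increment,NA,69,NA,NA
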