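population,component,usual_care,intervention
all,screening_diagnostics,48000,115000
all,anticoagulation,280000,410000
all,stroke_acute,1755000,1045000
all,longterm_disability,2025000,1460000
all,nonstroke_mace_hosp,730000,530000
women,total,5020000,3620000
men,total,4610000,3610000
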