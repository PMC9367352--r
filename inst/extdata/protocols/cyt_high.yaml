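name: cyt_high
drug: Cyt
dose_mg_per_kg: 62.5
days: "1-3"
evaluation_day: 12
mouse_mass_kg: 0.020
mu_AC: 0.012
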