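name: ibr_low
drug: Ibr
dose_mg_per_kg: 9
days: "1-5,8-10"
evaluation_day: 12
mouse_mass_kg: 0.020
mu_AC: 0.0041
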