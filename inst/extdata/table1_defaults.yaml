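# Reference defaults of the tumor-immune-drug model (rates per hour,
# amounts in cells or molecules per mouse). mu_AC / mu_C carry the
# high-dose cytarabine values; mu_CA keeps the tenfold linkage.
r: 0.01
K: 4.0e+6
mu_A: 2.0e-12
mu_AC: 0.012
a: 2.0e+3
mu_E: 4.0e-5
p: 4.0e-14
c: 1.0e+2
mu_EA: 4.0e-15
mu_EC: 417
b: 5.0e+6
mu_C: 0.231
mu_CA: 0.12
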