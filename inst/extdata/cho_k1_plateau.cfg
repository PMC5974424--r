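# CHO-K1 cell line, plateau-phase (density-arrested) culture, 250 kVp X-rays
# units: alpha0 Gy^-1, beta0 Gy^-2, repair_rate0 (= a + c) h^-1, gamma Gy
[params]
label = "cho-k1-plateau"
alpha0 = 0.155
beta0 = 0.048
repair_rate0 = 0.704
a_rate = 0
gamma = 0.924
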