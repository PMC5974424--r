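# CHO-K1 cell line, logarithmic growth phase, 250 kVp X-rays
# converted from the plateau-phase set via the DNA-content and repair-rate
# ratios (see convert_phase_parameters); values as published
[params]
label = "cho-k1-log"
alpha0 = 0.075
beta0 = 0.028
repair_rate0 = 1.782
a_rate = 0
gamma = 0.924
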