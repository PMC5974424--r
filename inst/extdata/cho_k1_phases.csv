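phase,g0g1_pct,s_pct,g2m_pct,g_rel,g2_rel,c_per_h
plateau,72.7,14.9,12.4,1.000,1.000,0.704
log,37.6,52.4,11.4,1.227,1.457,1.782
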