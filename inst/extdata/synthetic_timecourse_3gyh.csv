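# synthetic stand-in for a flow-cytometric cell-cycle time course during
# protracted exposure at 3.0 Gy/h: the S-phase fraction rises logistically
# by ~20 percentage points over 12 h from the plateau-phase baseline, with
# the relative mean DNA per nucleus coupled through the phase anchors.
# Generated by generate_synthetic_timecourse(magnitude = 20, t_max = 12).
time_h,s_fraction_pct,g_rel
0,14.9,1
2,16.4859733155429,1.00960042513675
4,19.794569421096,1.02962846022903
6,24.9,1.06053333333333
8,30.005430578904,1.09143820643763
10,33.3140266844571,1.11146624152991
12,34.9,1.12106666666667
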