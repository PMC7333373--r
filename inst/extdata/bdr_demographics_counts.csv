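variable,responders_1,nonresponders_1,responders_0,nonresponders_0,printed_p
bmi_obese,47,39,71,76,0.42
eod_any,65,49,53,66,0.08
pse,21,19,97,96,0.93
ses_mh,81,73,37,42,0.49
no2_hi,62,54,56,61,0.47
afr_hi,82,67,36,48,0.10
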