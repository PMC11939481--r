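term,estimate,se
threshold_1,10.281,3.880
threshold_2,12.119,3.935
riding_style=conservative,1.133,0.414
traffic_density=sparse,2.031,0.618
traffic_density=moderate,0.862,0.566
lane_fix_pct,0.105,0.040
pupil_cv,-9.560,4.778
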