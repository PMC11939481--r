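term,estimate,se
threshold_1,0.688,0.500
threshold_2,2.337,0.554
riding_style=conservative,1.234,0.402
traffic_density=sparse,1.792,0.591
traffic_density=moderate,0.787,0.547
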