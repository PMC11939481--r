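observed,distracted,scattered,focused
distracted,20,7,4
scattered,9,11,12
focused,2,11,21
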