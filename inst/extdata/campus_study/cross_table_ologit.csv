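observed,distracted,scattered,focused
distracted,18,6,7
scattered,12,7,13
focused,5,9,20
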