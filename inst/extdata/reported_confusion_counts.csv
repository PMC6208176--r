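decision,Q1,Q2,Q3,Q4
Q1,407,8,9,10
Q2,23,268,8,3
Q3,17,13,236,5
Q4,11,7,7,248
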