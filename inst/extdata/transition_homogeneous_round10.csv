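level,L1,L2,L3,L4,L5
L1,0.60,0.09,0.16,0.05,0.10
L2,0.14,0.33,0.29,0.09,0.15
L3,0.10,0.10,0.50,0.21,0.08
L4,0.07,0.03,0.23,0.49,0.18
L5,0.16,0.05,0.09,0.16,0.54
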