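level,L1,L2,L3,L4,L5
L1,0.70,0.17,0.11,0.01,0.01
L2,0.15,0.69,0.12,0.03,0.01
L3,0.10,0.12,0.68,0.05,0.05
L4,0.11,0.04,0.27,0.48,0.10
L5,0.10,0.02,0.07,0.05,0.76
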