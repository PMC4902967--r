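locus,Ho,He
L01,0.52,0.48
L02,0.61,0.50
L03,0.55,0.47
L04,0.70,0.55
L05,0.44,0.49
L06,0.58,0.51
L07,0.66,0.52
L08,0.49,0.46
L09,0.63,0.50
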