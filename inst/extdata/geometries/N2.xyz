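2
N2, r = 1.098 A
N      0.00000000     0.00000000     0.54900000
N      0.00000000     0.00000000    -0.54900000
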