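2
H2, r = 0.741 A
H      0.00000000     0.00000000     0.37050000
H      0.00000000     0.00000000    -0.37050000
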