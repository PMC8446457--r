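2
F2, r = 1.412 A
F      0.00000000     0.00000000     0.70600000
F      0.00000000     0.00000000    -0.70600000
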