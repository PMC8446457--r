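2
HF, r = 0.917 A
F      0.00000000     0.00000000     0.00000000
H      0.00000000     0.00000000     0.91700000
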