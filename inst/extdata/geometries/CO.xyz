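2
CO, r = 1.128 A
C      0.00000000     0.00000000     0.00000000
O      0.00000000     0.00000000     1.12800000
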