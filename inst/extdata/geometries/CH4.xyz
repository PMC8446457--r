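5
methane, r = 1.087 A
C      0.00000000     0.00000000     0.00000000
H      0.62757974     0.62757974     0.62757974
H      0.62757974    -0.62757974    -0.62757974
H     -0.62757974     0.62757974    -0.62757974
H     -0.62757974    -0.62757974     0.62757974
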