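8
ethane (staggered), CC 1.536 A, CH 1.091 A, CCH 111.2 deg
C      0.00000000     0.00000000     0.76800000
C      0.00000000     0.00000000    -0.76800000
H      1.01716527     0.00000000     1.16253241
H     -0.50858263     0.88089096     1.16253241
H     -0.50858263    -0.88089096     1.16253241
H      0.50858263     0.88089096    -1.16253241
H     -1.01716527     0.00000000    -1.16253241
H      0.50858263    -0.88089096    -1.16253241
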