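4
formaldehyde, CO 1.205 A, CH 1.111 A, HCH 116.2 deg
C      0.00000000     0.00000000     0.00000000
O      0.00000000     0.00000000     1.20500000
H      0.94320754     0.00000000    -0.58709499
H     -0.94320754     0.00000000    -0.58709499
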