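11
propane, CC 1.526 A, CCC 112.4 deg (idealized)
C     -1.26808230     0.00000000     0.84890711
C      0.00000000     0.00000000     0.00000000
C      1.26808230     0.00000000     0.84890711
H      0.00000000     0.87132000    -0.66527200
H      0.00000000    -0.87132000    -0.66527200
H     -2.16367311     0.00000000     0.21713729
H     -1.30986714     0.88612078     1.49253742
H     -1.30986714    -0.88612078     1.49253742
H      1.30986714     0.88612078     1.49253742
H      2.16367311     0.00000000     0.21713729
H      1.30986714    -0.88612078     1.49253742
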