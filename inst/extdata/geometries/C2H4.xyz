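6
ethylene, CC 1.339 A, CH 1.086 A, HCC 121.3 deg
C      0.66950000     0.00000000     0.00000000
C     -0.66950000     0.00000000     0.00000000
H      1.23369776     0.92794229     0.00000000
H      1.23369776    -0.92794229     0.00000000
H     -1.23369776     0.92794229     0.00000000
H     -1.23369776    -0.92794229     0.00000000
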