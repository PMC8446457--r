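6
methanol, CO 1.427 A, OH 0.956 A, COH 108.9 deg (idealized)
C      0.00000000     0.00000000     0.00000000
O      1.42700000     0.00000000     0.00000000
H      1.73666505     0.90445760     0.00000000
H     -0.36533333     0.51665935     0.89488025
H     -0.36533333    -1.03331871     0.00000000
H     -0.36533333     0.51665935    -0.89488025
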