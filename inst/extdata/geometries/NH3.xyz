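4
ammonia, r = 1.012 A, angle = 106.7 deg
N      0.00000000     0.00000000     0.00000000
H      0.00000000     0.93752957     0.38102795
H     -0.81192443    -0.46876479     0.38102795
H      0.81192443    -0.46876479     0.38102795
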