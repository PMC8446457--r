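3
water, r = 0.9572 A, angle = 104.52 deg
O      0.00000000     0.00000000     0.00000000
H      0.00000000     0.75695033    -0.58588228
H      0.00000000    -0.75695033    -0.58588228
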