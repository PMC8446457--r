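5
chloromethane, CCl 1.785 A, CH 1.090 A, HCCl 108.4 deg
C      0.00000000     0.00000000     0.00000000
Cl     0.00000000     0.00000000     1.78500000
H      1.03427485     0.00000000    -0.34405745
H     -0.51713743     0.89570830    -0.34405745
H     -0.51713743    -0.89570830    -0.34405745
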