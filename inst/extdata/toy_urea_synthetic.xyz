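13
synthetic urea-phenyl toy fixture (constructed, not optimized)
C         1.390000       0.000000       0.000000
C         0.695000       1.203775       0.000000
C        -0.695000       1.203775       0.000000
C        -1.390000       0.000000       0.000000
C        -0.695000      -1.203775       0.000000
C         0.695000      -1.203775       0.000000
N         2.800000       0.000000       0.000000
H         2.295000       0.874686       0.000000
C         3.490000      -1.195115       0.000000
O         2.880000      -2.251666       0.000000
N         4.870000      -1.195115       0.000000
H         5.375000      -2.069801       0.000000
H         5.375000      -0.320429       0.000000
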