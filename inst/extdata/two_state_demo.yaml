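# Two-state switching backbone: a helix-like state and its antipodal
# counterpart (equal encoded covariance), stationary distribution 3:1.
states:
  phiMeanDeg: [[-57, -57, -57, -57, -57, -57], [123, 123, 123, 123, 123, 123]]
  psiMeanDeg: [[-47, -47, -47, -47, -47, -47], [133, 133, 133, 133, 133, 133]]
  kappa: 200
chain:
  transition: [[0.85, 0.15], [0.45, 0.55]]
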