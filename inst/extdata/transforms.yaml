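# Default reference-space transforms (homogeneous 4x4 affines, mm).
#
# The shipped Talairach -> MNI matrix is a Lancaster-style pooled affine.
# Its entries are approximate published estimates; they are configuration,
# not code — replace or re-register them if your data were normalised with a
# different template or transform. The reverse direction is the exact matrix
# inverse.
transforms:
  - name: tal2mni
    from: TAL
    to: MNI
    matrix:
      - [ 0.9357,  0.0029, -0.0072, -1.0423]
      - [-0.0065,  0.9396, -0.0726, -1.3940]
      - [ 0.0103,  0.0752,  0.8967,  3.6475]
      - [ 0.0,     0.0,     0.0,     1.0]
  - name: mni2tal
    from: MNI
    to: TAL
    inverse_of: tal2mni
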