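sources:
- lFEF
- rFEF
- lIPS
- rIPS
- rTPJ
edges:
- from: rTPJ
  to: lFEF
  type: forward
  effect: 1
- from: rTPJ
  to: rFEF
  type: forward
  effect: 2
- from: lIPS
  to: lFEF
  type: forward
  effect: ~
- from: rIPS
  to: rFEF
  type: forward
  effect: ~
- from: lFEF
  to: rTPJ
  type: backward
  effect: 3
- from: rFEF
  to: rTPJ
  type: backward
  effect: 4
- from: lFEF
  to: lIPS
  type: backward
  effect: ~
- from: rFEF
  to: rIPS
  type: backward
  effect: ~
input_targets:
- rTPJ
- lIPS
- rIPS
design:
  condition:
  - early
  - late
  covariate:
  - 0.0
  - 1.0
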