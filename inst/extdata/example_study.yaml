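# Example simulated artifact-quantification study: one conventional EID
# acquisition (threshold source) plus photon-counting Macro and Chess
# high-energy threshold images at the same tube potential.
simulate: true
seed: 42
k_sd: 3
margins_mm:
  cortical_bone: 2
  bone_marrow: 2
  water: 30
phantom:
  voxel_spacing_mm: [1.0, 1.0, 2.0]
artifact:
  target_percent: 10
series:
  - protocol: EID-CT 140
  - protocol: Macro-HTI 140/75
  - protocol: Chess-HTI 140/75
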