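# Synthetic ORF1p coiled coil annotation (residue coordinates, 1-based).
cc_start: 46
cc_end: 146
n_heptads: 14
stammer_heptad: 6
regions:
  region1: [1, 104]
  region2: [105, 152]
  region3: [153, 338]
  cc: [46, 146]
  ntd: [1, 45]
  cterm: [147, 338]
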