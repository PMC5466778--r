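# S59 bursting in the VT1 muscle: about 23% of nuclei active at stage 15.
name: vt1_s59_stage15
muscle: VT1
template: band
genes:
  - gene: S59
    p_on: {12: 1.0, 13: 0.3, 14: 0.25, 15: 0.23, 16: 0.1}
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
geometry:
  nuclei_by_stage: {12: 1, 13: 3, 14: 5, 15: 6, 16: 7}
recovery:
  - quantity: active_fraction
    gene: S59
    stage: 15
    tolerance_se: 3
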