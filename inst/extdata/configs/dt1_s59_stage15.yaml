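# S59 bursting in the DT1 muscle: about 45% of nuclei actively transcribing
# at stage 15.
name: dt1_s59_stage15
muscle: DT1
template: band
genes:
  - gene: S59
    p_on: {12: 1.0, 13: 0.35, 14: 0.4, 15: 0.45, 16: 0.2}
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
recovery:
  - quantity: active_fraction
    gene: S59
    stage: 15
    tolerance_se: 3
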