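# S59 bursting in the VA2 muscle: about 27% of nuclei active at stage 15.
# Ventral muscles carry fewer nuclei than the dorsolateral DT1.
name: va2_s59_stage15
muscle: VA2
template: band
genes:
  - gene: S59
    p_on: {12: 1.0, 13: 0.3, 14: 0.3, 15: 0.27, 16: 0.15}
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
geometry:
  nuclei_by_stage: {12: 1, 13: 3, 14: 6, 15: 8, 16: 9}
recovery:
  - quantity: active_fraction
    gene: S59
    stage: 15
    tolerance_se: 3
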