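# kon (realisation gene) in DT1: dot number rises to an average of 4.35 per
# fibre at stage 15 (10 nuclei x burst probability 0.435).
name: dt1_kon_stage15
muscle: DT1
template: band
genes:
  - gene: kon
    p_on: {12: 1.0, 13: 0.25, 14: 0.3, 15: 0.435, 16: 0.25}
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
recovery:
  - quantity: mean_dots
    gene: kon
    stage: 15
    tolerance_rel: 0.10
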