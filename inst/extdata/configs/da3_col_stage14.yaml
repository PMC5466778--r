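# col transcription in the DA3 muscle around stage 14: stochastic bursting in
# syncytial nuclei plus persistent high-level transcription in the founder-cell
# nucleus (9-fold intensity multiplier).
name: da3_col_stage14
muscle: DA3
template: da3_angled
genes:
  - gene: col
    p_on: {12: 1.0, 13: 0.6, 14: 0.5, 15: 0.4, 16: 0.05}
    p_on_fc: 1.0
    fc_restricted: false
    fc_multiplier: 9.0
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
recovery:
  - quantity: fc_intensity_ratio
    gene: col
    stage: 14
    tolerance_rel: 0.15
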