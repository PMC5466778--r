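# Kr: transcribed at a constant level in a single nucleus per fibre (the
# founder cell) from stage 12 to 14, never propagated to syncytial nuclei.
name: kr_stage13
muscle: LL1
template: band
genes:
  - gene: Kr
    p_on: {12: 0.0, 13: 0.0, 14: 0.0, 15: 0.0, 16: 0.0}
    p_on_fc: 1.0
    fc_restricted: true
    intensity_mean: 20000
    intensity_cv: 0.1
joint_tables: []
recovery:
  - quantity: mean_dots
    gene: Kr
    stage: 13
    tolerance_abs: 0.0
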