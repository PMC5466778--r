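# Pax (realisation gene): activated only post fusion (no FC dot at stage 12),
# peaking at a mean of 2.5 dots per fibre at stage 15.
name: pax_stage_course
muscle: DA3
template: band
genes:
  - gene: Pax
    p_on: {12: 0.0, 13: 0.1, 14: 0.15, 15: 0.25, 16: 0.1}
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
recovery:
  - quantity: mean_dots
    gene: Pax
    stage: 15
    tolerance_rel: 0.10
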