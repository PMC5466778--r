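# Con in DA3: transcribed in a single nucleus per fibre (the founder cell),
# whose position is only statistically stereotyped - drawn uniformly over
# the angled DA3 outline. Under the subdomain rule the template geometry
# places about 70% of such dots in the central subdomain.
name: da3_con_stage14
muscle: DA3
template: da3_angled
genes:
  - gene: Con
    p_on: {12: 0.0, 13: 0.0, 14: 0.0, 15: 0.0, 16: 0.0}
    p_on_fc: 1.0
    fc_restricted: true
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
geometry:
  fc_position: uniform
recovery:
  - quantity: central_pct
    gene: Con
    stage: 14
    tolerance_se: 3
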