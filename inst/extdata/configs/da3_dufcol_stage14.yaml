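# Double FISH of duf and col in stage-14 DA3 syncytia. Bursting of the two
# genes is correlated: 80% of nuclei transcribe at least one, and 50% of
# those transcribe both - infeasible under independence, hence the joint
# table. Counted with the permissive detection profile (all dots count,
# even small and weak).
name: da3_dufcol_stage14
muscle: DA3
template: da3_angled
genes:
  - gene: duf
    p_on: {12: 1.0, 13: 0.6, 14: 0.6, 15: 0.3, 16: 0.05}
    intensity_mean: 20000
    intensity_cv: 0.2
  - gene: col
    p_on: {12: 1.0, 13: 0.6, 14: 0.6, 15: 0.4, 16: 0.05}
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables:
  - genes: [duf, col]
    p: {both: 0.4, a_only: 0.2, b_only: 0.2, neither: 0.2}
detection:
  profile: permissive
recovery:
  - quantity: union_pct
    stage: 14
    tolerance_se: 3
  - quantity: co_given_active_pct
    stage: 14
    tolerance_se: 3
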