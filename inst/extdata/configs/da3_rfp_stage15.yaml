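# Lineage-tracing mixing in DA3: fusion-competent myoblasts recruited from a
# pool in which about 50% carry the heritable RFP label, so about 50% of
# fibre nuclei are RFP+.
name: da3_rfp_stage15
muscle: DA3
template: da3_angled
genes:
  - gene: col
    p_on: {12: 1.0, 13: 0.6, 14: 0.5, 15: 0.4, 16: 0.05}
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
lineage:
  p_labelled: 0.5
  labelled_intensity: 100
  unlabelled_intensity: 20
  threshold: 60
recovery:
  - quantity: labelled_pct
    stage: 15
    tolerance_se: 3
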