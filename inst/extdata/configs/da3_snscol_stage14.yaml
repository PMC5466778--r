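# Mutually exclusive programmes: sns (the FCM programme) is never
# co-transcribed with col in one nucleus; repression of the FCM programme
# precedes activation of the fibre programme after fusion.
name: da3_snscol_stage14
muscle: DA3
template: da3_angled
genes:
  - gene: sns
    p_on: {12: 0.0, 13: 0.15, 14: 0.1, 15: 0.05, 16: 0.0}
    exclusion_group: fcm_programme
    intensity_mean: 20000
    intensity_cv: 0.2
  - gene: col
    p_on: {12: 1.0, 13: 0.6, 14: 0.5, 15: 0.4, 16: 0.05}
    exclusion_group: fcm_programme
    intensity_mean: 20000
    intensity_cv: 0.2
joint_tables: []
detection:
  profile: permissive
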