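# Example ribbonfd configuration: simulated two-group cohort.
# For mode: volumes, supply instead
#   subjects: [{subject_id: s01, path: s01.nii.gz, group: adolescent, sex: female}, ...]
#   atlas: atlas_8lobe_example.json
mode: simulate
seed: 1
methods: [BC, MB]
cohort:
  size: 64
  n:
    adolescent_female: 11
    adolescent_male: 6
    adult_female: 7
    adult_male: 7
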