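# Paired bilateral cohort: 75 subjects, both shoulders. Nondominant vault
# version 8.2 deg with a +1.4 deg dominance shift; subject baseline SD
# 2.25 deg and within-subject SD 1.5 deg give a marginal SD of 2.7 deg.
n_shoulders: 150
vault_version_mean_deg: 8.2
vault_version_sd_deg: 2.7
body_offset_mean_deg: 7.8
body_offset_sd_deg: 1.72
paired: true
dominance_shift_deg: 1.4
between_subject_sd_deg: 2.25
within_subject_sd_deg: 1.5
inclination_range_deg: [0.0, 30.0]
landmark_noise_sd_mm: 0.0
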