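# Normal-shoulder cohort: vault version 8.9 +/- 2.7 deg; body-shape offset
# 7.8 +/- 1.72 deg so that conventional version is 1.1 +/- 3.2 deg.
n_shoulders: 150
vault_version_mean_deg: 8.9
vault_version_sd_deg: 2.7
body_offset_mean_deg: 7.8
body_offset_sd_deg: 1.72
paired: false
dominance_shift_deg: 0.0
inclination_range_deg: [0.0, 30.0]
landmark_noise_sd_mm: 0.0
prop_left: 0.5
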