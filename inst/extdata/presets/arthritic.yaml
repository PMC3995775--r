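# Arthritic-shoulder cohort: vault version 18.2 +/- 9.1 deg; body-shape
# offset 7.4 +/- 1.92 deg so that conventional version is 10.8 +/- 9.3 deg.
# All synthetic arthritic shoulders use the standard glenoid line (the B2
# intermediate-line subgroup is not modelled separately).
n_shoulders: 150
vault_version_mean_deg: 18.2
vault_version_sd_deg: 9.1
body_offset_mean_deg: 7.4
body_offset_sd_deg: 1.92
paired: false
dominance_shift_deg: 0.0
inclination_range_deg: [0.0, 30.0]
landmark_noise_sd_mm: 0.0
prop_left: 0.5
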