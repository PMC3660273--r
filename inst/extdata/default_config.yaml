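# Default matched FF/FFPET cohort simulation: 16 breast-tumor pairs
# (8 ER+, 8 ER-), three FFPET amplification kits ordered by degradation
# severity (nugen < affy2c < wta). Fields map 1:1 to sim_config().
seed: 1
n_genes: 200
transcript_length_range: [600, 1200]
probe_sets_per_gene:
  "1": 0.70
  "2": 0.25
  "3": 0.05
probes_per_set: 11
probe_length: 25
frac_nonmatching_probes: 0.05
frac_crosshyb_probes: 0.03
n_complete_mismatch_sets: 60
n_pairs_per_group: 8
frac_de_genes: 0.2
effect_range: [1.2, 3.0]
frac_silent_genes: 0.3
background_mean: 50.0
background_sd: 10.0
probe_affinity_sd: 0.3
measurement_sd_ff: 0.25
baseline_mean: 8.0
baseline_sd: 1.5
tissue_sd: 0.3
control_transcript_length: 1998
control_probe_spacing: 18
kit_profiles:
  nugen:
    three_prime_decay: 0.0015
    extra_noise_sd: 0.3
    dropout_prob: 0.02
    global_attenuation: 0.5
  affy2c:
    three_prime_decay: 0.003
    extra_noise_sd: 0.6
    dropout_prob: 0.05
    global_attenuation: 1.0
  wta:
    three_prime_decay: 0.006
    extra_noise_sd: 1.2
    dropout_prob: 0.12
    global_attenuation: 2.0
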