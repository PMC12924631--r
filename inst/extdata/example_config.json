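{
  "n_pigs_per_sex": 4,
  "n_replications": 50,
  "temperature": 18,
  "noise_cv": 0.05,
  "seed": 7
}
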