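{
  "seed": 1,
  "out_dir": "gapsel_study",
  "simulate": {
    "n_founders": 120,
    "n_chromosomes": 17,
    "n_snps": 1500,
    "progeny_per_cross": 10,
    "missing_rate": 0.04
  },
  "cv": { "k": 5, "repeats": 2 }
}
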