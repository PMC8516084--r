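# Public MALDI-MS bacterial benchmark (requires a local download from the
# UCI Machine Learning Repository); Gram-positive vs Gram-negative on raw
# abundances after removing features with no signal anywhere.
name: micromass-uci
dataset:
  path: data/micromass_gram.arff
  label_column: class
preprocess:
  drop_zero: true
sizes: {n_low: 130, n_hi: 130}
protocol: loo
seed: 1
output: out/micromass-uci
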