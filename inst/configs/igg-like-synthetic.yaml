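# Small glycopeptide-like table: 21 samples per class, 15 features with a
# subtle 20% shift on the first four, per-sample multiplicative drift.
name: igg-like-synthetic
dataset:
  synthetic: drift_table
  args: {n_per_class: 21, n_features: 15}
preprocess:
  scale: true
sizes: {n_low: 9, n_hi: 9}
protocol: loo
seed: 1
output: out/igg-like-synthetic
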