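# Satellite-like imbalance: ~10% minority. The base SVM collapses to the
# majority-state model on a fraction of seeds; a local model ratioed toward
# the minority (10 low, 5 hi) recovers it. Run with `lbm compare`.
name: imbalanced-clouds
dataset:
  synthetic: imbalanced_clouds
  args: {seed: 2}
preprocess: {}
sizes: {n_low: 10, n_hi: 5}
protocol: loo
seed: 1
output: out/imbalanced-clouds
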