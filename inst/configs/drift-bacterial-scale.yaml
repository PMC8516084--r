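# Intensity-drift table at bacterial-typing scale (raw abundances): the
# bundled condition under which the local-balanced model's AUC advantage
# over the base SVM is measured across seeds.
name: drift-bacterial-scale
dataset:
  synthetic: drift_table
  args: {n_per_class: 100, n_features: 50, effect_size: 0.2,
         effect_features: [1,2,3,4,5,6,7,8,9,10,11,12], noise_sd: 0.08}
preprocess: {}
sizes: {n_low: 50, n_hi: 50}
protocol: loo
seed: 1
output: out/drift-bacterial-scale
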