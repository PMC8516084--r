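# Noisy hill/valley traces (structural stand-in for the public benchmark).
name: hill-valley-synthetic
dataset:
  synthetic: hill_valley
  args: {n_samples: 200}
preprocess:
  scale: true
sizes: {n_low: 60, n_hi: 60}
protocol: loo
seed: 1
output: out/hill-valley-synthetic
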