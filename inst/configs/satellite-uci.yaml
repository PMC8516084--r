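# Public satellite land-cover benchmark (requires a local download from the
# UCI Machine Learning Repository). Convert sat.trn + sat.tst to one CSV
# with a header row and a `class` column first, e.g. with lbm convert
# tooling of your choice; target class 4 vs rest, sizes (10, 18).
name: satellite-uci
dataset:
  path: data/satellite.csv
  label_column: class
  binarize_target: "4"
preprocess:
  scale: true
sizes: {n_low: 10, n_hi: 18}
protocol: loo
seed: 1
output: out/satellite-uci
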