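# Example synthetic-data configuration for `clinstack generate`.
schema: uci
n_rows: 500
informative_features: [age, cp, chol, oldpeak, thal]
effect_sizes: [1.2, 0.9, -0.8, 0.8, 0.7]
label_balance: 0.5446
missing_rate: 0.02
duplicate_count: 1
outlier_count: 5
seed: 1
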