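# Example end-to-end run configuration for `clinstack run`.
schema: uci
preprocess:
  impute_method: knn
  knn_k: 5
  outlier_method: isolation_forest
  contamination: 0.05
  rebalance_method: none
  normality_alpha: 0.05
  skew_threshold: 1.0
  seed: 1
selection:
  x: 13
  methods: [pearson, anova, rfe, lasso, tree]
base_models:
  - model_id: lr
  - model_id: svm
  - model_id: xgb
  - model_id: rf
  - model_id: dnn
  - model_id: cnn
stacking:
  oof_folds: 5
  combiner: proposed
evaluation:
  k: 10
  seed: 1
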