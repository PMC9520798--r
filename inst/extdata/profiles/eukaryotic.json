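{
  "profile": "eukaryotic",
  "window": 31,
  "k": 140,
  "algorithm": "svm_rbf",
  "folds": 10,
  "identity_threshold": 0.9
}
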