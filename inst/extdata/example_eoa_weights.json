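{
  "intercept": 10,
  "w_metric": 1,
  "w_cluster": 1,
  "w_gesture": 0.25
}
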