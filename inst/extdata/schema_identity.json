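{
  "ga_weeks": "ga_weeks",
  "sex": "sex",
  "bw_g": "bw_g",
  "pnd_days": "pnd_days",
  "treated": "treated"
}
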