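{
  "ln_I0": -11.00,
  "b": 0.6518,
  "E_A": 0.7015,
  "E_C": 0,
  "b_C": 0,
  "E_AC": 0,
  "plasticity_enabled": false
}
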