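{
  "ln_I0": -11.03,
  "b": 0.6307,
  "E_A": 0.7217,
  "E_C": -0.1709,
  "b_C": -0.0741,
  "E_AC": 0.1124,
  "plasticity_enabled": true
}
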