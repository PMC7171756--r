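model:
  horizon_cycles: 84
  cycle_length: 1
  annual_discount_rate: 0.03
  half_cycle_correction: false
utilities:
  stable: 0.76
  progressive: 0.68
fixture:
  weibull_shape: 1.3
  censor_rate: 0.2
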