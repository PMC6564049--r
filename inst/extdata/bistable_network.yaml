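# Bistable slow-HAP + DAP network (100 neurons)
vmn1: 100
esyn_1: 0.25
syntrans: 0.5
delta_min: 5
delta_range: 10
n_h: 3
type1:
  I_re: 100
  I_ratio: 0.5
  k_HAP: 30
  lambda_HAP: 40
  k_DAP: 0.75
  lambda_DAP: 750
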