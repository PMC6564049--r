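# Two-cell-type oscillatory network: 100 interconnected slow-HAP neurons
# driving 100 fast-HAP neurons
vmn1: 100
vmn2: 100
esyn_1: 0.35
esyn_12: 0.2
syntrans: 0.5
delta_min: 5
delta_range: 15
n_h: 3
type1:
  I_re: 180
  I_ratio: 0.5
  k_HAP: 60
  lambda_HAP: 50
type2:
  I_re: 80
  I_ratio: 0.5
  k_HAP: 60
  lambda_HAP: 5
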