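# example scenario grid for `carscreen evaluate --config ...`
n: 250
d: 60
rel_var: 0.1
exp_var: 0.5
cens_rate: 0.25
signal_block: [1, 3]
family: lognormal
replications: 10
base_seed: 1
pilot_size: 50000
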