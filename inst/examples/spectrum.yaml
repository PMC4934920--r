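# height-fluctuation spectrum of a flat patch at fixed vertex count
out_dir: spectrum_out
kappa: 20
gamma: 0
gc: false
patch_L: 146
target_edge: 8
sweeps: 80000
warmup: 15000
record_every: 80
seed: 1
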