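# fugacity -> surface tension calibration (tube-radius route)
out_dir: calibrate_out
kappa: 20
z_values: [0.006, 0.010, 0.016, 0.025]
patch_L: 140
target_edge: 8
method: tube
sweeps: 45000
warmup: 6000
seed: 1
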