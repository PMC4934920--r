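# membrane tube pulling / force-extension at calibrated tension
out_dir: pull_out
kappa: 20
z: 0.012
L_targets: [30, 60, 90, 105]
stiffness: 0.5
sweeps: 20000
warmup: 6000
patch_L: 140
target_edge: 8
seed: 1
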