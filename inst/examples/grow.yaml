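# 10-filament bundling and tube formation
out_dir: grow_out
kappa: 20
z: 0.005
N_fil: 10
std: 0          # polar-angle spread (degrees); 20 / 40 for disorder runs
depth: 50
kon0: 1
koff: 0.01
nu: 100
max_time: 2500
stop_height: 260
central_frozen_node: false   # true reproduces the screening experiment
patch_L: 140
target_edge: 8
seed: 1
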