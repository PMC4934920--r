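# reduced-model first passage for the bending transition
out_dir: fpt_out
theta: 45
L0: 60
kappa: 20
gamma: 0.01
Lp: 15000
kon0: 1
koff: 0.01
patch_L: 140
theta_range: [10, 20, 30, 45, 60]
L0_range: [40, 60, 80]
seed: 1
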