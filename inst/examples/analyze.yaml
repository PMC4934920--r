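# tube metrics from a stored mesh frame
out_dir: analyze_out
mesh: final_mesh.ply
kappa: 20
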