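comparison,gp_bf
H1_vs_u,0.510
H2_vs_u,0.910
H3_vs_u,1.125
H4_vs_u,0.949
H1_vs_c,0.511
H2_vs_c,1.014
H3_vs_c,1.235
H4_vs_c,1.412
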