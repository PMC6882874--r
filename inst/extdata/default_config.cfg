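# default design configuration (lengths in nm unless stated)
rise_per_bp = 0.34
bp_per_turn = 10.5
min_edge_bp = 42
interhelix_distance = 2.5
unpaired_nt_spacing = 0.42
crossover_end_guard_bp = 10
staple_min_nt = 20
staple_max_nt = 60
nick_domain_min_bp = 7
staple_xover_min_sep_bp = 8
mesh_type = triangular
seed = 1
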