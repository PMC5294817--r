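n_shared	n_only_a	n_only_b	min_fraction	reciprocal
6	69	50	0.25	FALSE
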