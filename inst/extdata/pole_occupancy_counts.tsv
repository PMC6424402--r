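od600	n_poles	n_both	n_filaments_only	n_relics_only	n_neither
0.25	44	21	19	0	4
1.0	25	9	0	3	13
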