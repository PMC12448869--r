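name	model_archive	reference_pdb	reference_chain	glycan_residues	atom_filter	printed_rmsd_A
man1a1-m9-3arm	ma-af3glycan	5KKB	A	3,4,6,9	heavy	0.284
b3galt5-core3	ma-af3glycan	8ZX3	A	1,2	heavy	0.096
pp2-chitotriose	ma-af3glycan	7W4B	A	1,2,3	heavy	0.252
bc2lc-globoh	ma-af3glycan	6TIG	A	4,5,6	heavy	0.137
siglec2-cis	ma-af3glycan	5VKM	A	9,11	heavy	0.292
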