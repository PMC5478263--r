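genome	shared_locations	singleton_locations	pair_locations	triplet_locations	new_location_genes
reference	20	15	5	0	0
CBS5557	20	12	7	1	3
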