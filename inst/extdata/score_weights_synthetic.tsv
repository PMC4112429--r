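snp_id	effect_allele	other_allele	weight	provenance
ldl_snp01	A	G	0.134758306992522	synthetic
ldl_snp02	A	G	0.0898388713283479	synthetic
ldl_snp03	A	G	0.0628872099298435	synthetic
ldl_snp04	A	G	0.0539033227970087	synthetic
ldl_snp05	A	G	0.0539033227970087	synthetic
ldl_snp06	A	G	0.0449194356641739	synthetic
ldl_snp07	A	G	0.0449194356641739	synthetic
ldl_snp08	A	G	0.0359355485313392	synthetic
ldl_snp09	A	G	0.0359355485313392	synthetic
ldl_snp10	A	G	0.161709968391026	synthetic
ldl_snp11	A	G	0.0269516613985044	synthetic
ldl_snp12	A	G	0.0359355485313392	synthetic
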