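gene	chrom	pos	ref	alt	hgvs_c	pathogenicity
LDLR	19	11216230	C	T	c.1060C>T	known_fh
LDLR	19	11217315	G	A	c.1432G>A	known_fh
LDLR	19	11218100	TACA	T	c.2140_2142del	known_fh
LDLR	19	11221440	C	A	c.2054C>A	known_fh
APOB	2	21229160	C	T	c.10580G>A	known_fh
PCSK9	1	55518316	G	T	c.1120G>T	known_fh
LDLRAP1	1	25870520	T	TA	c.432_433insA	known_fh
APOB	2	21230600	G	A	c.148G>A	unknown_effect
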