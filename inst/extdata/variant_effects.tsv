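locus	gene	chromosome	inheritance	allele	effect	freq
rs11178998	TPH2	autosomal	additive	A	1	0.95
rs11178998	TPH2	autosomal	additive	G	3	0.05
rs4290270	TPH2	autosomal	additive	T	1	0.63
rs4290270	TPH2	autosomal	additive	A	0.7	0.37
rs7305115	TPH2	autosomal	additive	G	1	0.60
rs7305115	TPH2	autosomal	additive	A	1.7	0.40
HTTLPR	SLC6A4	autosomal	dominant	L	1	0.58
HTTLPR	SLC6A4	autosomal	dominant	S	0.3	0.42
uVNTR	MAOA	X-linked	additive	3R	0.2	0.302
uVNTR	MAOA	X-linked	additive	3.5R	1	0.004
uVNTR	MAOA	X-linked	additive	4R	1	0.685
uVNTR	MAOA	X-linked	additive	5R	0.2	0.009
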