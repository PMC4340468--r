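##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	DEMO
10	96741053	rs1057910	A	C	.	PASS	.	GT	0/1
10	96741058	rs1057911	A	T	.	PASS	.	GT	0/0
10	96702047	rs1799853	C	T	.	PASS	.	GT	0/0
10	96709038	rs2256871	A	G	.	PASS	.	GT	0/0
16	31107689	rs9923231	C	T	.	PASS	.	GT	1/1
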