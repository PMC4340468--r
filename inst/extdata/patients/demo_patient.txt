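# demo patient: CYP2C9 *1/*3 heterozygote, VKORC1 rs9923231 T/T
# rsid	chromosome	position	genotype
rs1057910	10	96741053	AC
rs1057911	10	96741058	AA
rs1799853	10	96702047	CC
rs2256871	10	96709038	AA
rs9923231	16	31107689	TT
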