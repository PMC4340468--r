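Haplotype	rs1057910	rs1057911	rs1799853	rs2256871
CYP2C9*1	A	A	C	A
CYP2C9*3	C			
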