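child	parent	gene
TPMT*3A	TPMT*3	TPMT
TPMT*3B	TPMT*3	TPMT
TPMT*3C	TPMT*3	TPMT
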