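rsid	gene	orientation	alleles	assays	seeAlso
rs1057910	CYP2C9	forward	A,C	23andMe_v3	http://bio2rdf.org/dbsnp:rs1057910
rs1057911	CYP2C9	forward	A,T	23andMe_v3	http://bio2rdf.org/dbsnp:rs1057911
rs1799853	CYP2C9	forward	C,T	23andMe_v3	http://bio2rdf.org/dbsnp:rs1799853
rs2256871	CYP2C9	forward	A,G	23andMe_v3	http://bio2rdf.org/dbsnp:rs2256871
rs9923231	VKORC1	forward	C,T	23andMe_v3	http://bio2rdf.org/dbsnp:rs9923231
rs90000001	TPMT	forward	G,A	synthetic_panel	
rs90000002	TPMT	forward	C,T	synthetic_panel	
rs90000003	TPMT	forward	T,C	synthetic_panel	
rs90000004	TPMT	forward	A,G	synthetic_panel	
rs90000005	TPMT	forward	G,A	synthetic_panel	
rs90000006	TPMT	forward	C,T	synthetic_panel	
rs90000007	TPMT	forward	T,C	synthetic_panel	
rs90000008	TPMT	forward	A,G	synthetic_panel	
rs90000009	TPMT	forward	G,A	synthetic_panel	
rs90000010	TPMT	forward	C,T	synthetic_panel	
rs90000011	TPMT	forward	T,C	synthetic_panel	
rs90000012	TPMT	forward	A,G	synthetic_panel	
rs90000013	TPMT	forward	G,A	synthetic_panel	
rs90000014	TPMT	forward	C,T	synthetic_panel	
rs90000015	TPMT	forward	T,C	synthetic_panel	
rs90000016	TPMT	forward	A,G	synthetic_panel	
rs90000017	TPMT	forward	G,A	synthetic_panel	
rs90000018	TPMT	forward	C,T	synthetic_panel	
rs90000019	TPMT	forward	T,C	synthetic_panel	
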