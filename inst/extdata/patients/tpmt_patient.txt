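# demo patient: TPMT *1/*3A heterozygote on the synthetic panel
# rsid	chromosome	position	genotype
rs90000001	6	18130001	GG
rs90000002	6	18130002	CT
rs90000003	6	18130003	TT
rs90000004	6	18130004	AA
rs90000005	6	18130005	GG
rs90000006	6	18130006	CC
rs90000007	6	18130007	TT
rs90000008	6	18130008	AA
rs90000009	6	18130009	GG
rs90000010	6	18130010	CC
rs90000011	6	18130011	TT
rs90000012	6	18130012	AA
rs90000013	6	18130013	GG
rs90000014	6	18130014	CC
rs90000015	6	18130015	TT
rs90000016	6	18130016	AA
rs90000017	6	18130017	GG
rs90000018	6	18130018	CC
rs90000019	6	18130019	TT
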