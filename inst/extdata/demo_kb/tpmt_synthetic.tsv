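Haplotype	rs90000001	rs90000002	rs90000003	rs90000004	rs90000005	rs90000006	rs90000007	rs90000008	rs90000009	rs90000010	rs90000011	rs90000012	rs90000013	rs90000014	rs90000015	rs90000016	rs90000017	rs90000018	rs90000019
TPMT*1	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*2	A	C	T	A	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*3A	G	T	T	A	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*3B	G	C	C	A	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*3C	G	C	T	G	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*4	G	C	T	A	A	C	T	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*5	G	C	T	A	G	T	T	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*6	G	C	T	A	G	C	C	A	G	C	T	A	G	C	T	A	G	C	T
TPMT*7	G	C	T	A	G	C	T	G	G	C	T	A	G	C	T	A	G	C	T
TPMT*8	G	C	T	A	G	C	T	A	A	C	T	A	G	C	T	A	G	C	T
TPMT*9	G	C	T	A	G	C	T	A	G	T	T	A	G	C	T	A	G	C	T
TPMT*10	G	C	T	A	G	C	T	A	G	C	C	A	G	C	T	A	G	C	T
TPMT*11	G	C	T	A	G	C	T	A	G	C	T	G	G	C	T	A	G	C	T
TPMT*12	G	C	T	A	G	C	T	A	G	C	T	A	A	C	T	A	G	C	T
TPMT*13	G	C	T	A	G	C	T	A	G	C	T	A	G	T	T	A	G	C	T
TPMT*14	G	C	T	A	G	C	T	A	G	C	T	A	G	C	C	A	G	C	T
TPMT*15	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T	G	G	C	T
TPMT*16	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T	A	A	C	T
TPMT*17	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T	A	G	T	T
TPMT*18	G	C	T	A	G	C	T	A	G	C	T	A	G	C	T	A	G	C	C
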