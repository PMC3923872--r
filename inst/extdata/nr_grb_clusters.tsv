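# HCNE-based GRB cluster assignment of the 48 human nuclear receptor genes,
# with homology-based subfamily (0, I-VI) and mechanism class
# (NHR = nuclear hormone receptor, NOR = nuclear orphan receptor).
# cluster 1 = high HCNE density (putative GRB targets), cluster 2 = low.
gene	cluster	subfamily	mechanism
NR1D1	1	I	NHR
RARA	1	I	NHR
THRA	1	I	NHR
NR4A3	1	IV	NOR
NR6A1	1	VI	NOR
NR1D2	1	I	NHR
RARB	1	I	NHR
THRB	1	I	NHR
RARG	1	I	NHR
HNF4G	1	II	NHR
NR0B1	1	0	NOR
NR2E1	1	II	NOR
NR5A1	1	V	NHR
RORA	1	I	NHR
RORB	1	I	NHR
NR0B2	1	0	NOR
NR4A2	1	IV	NOR
ESRRG	1	III	NOR
NR5A2	1	V	NHR
NR2F1	1	II	NOR
NR2F2	1	II	NOR
NR4A1	1	IV	NOR
RXRG	1	II	NHR
PPARG	1	I	NHR
ESRRB	1	III	NOR
NR1H3	2	I	NHR
AR	2	III	NHR
NR2C1	2	II	NOR
RORC	2	I	NHR
NR2E3	2	II	NOR
NR1I2	2	I	NHR
NR1H4	2	I	NHR
ESR1	2	III	NHR
ESR2	2	III	NHR
NR2C2	2	II	NOR
NR1H2	2	I	NHR
PGR	2	III	NHR
RXRA	2	II	NHR
NR3C1	2	III	NHR
NR3C2	2	III	NHR
PPARD	2	I	NHR
VDR	2	I	NHR
NR1I3	2	I	NHR
RXRB	2	II	NHR
NR2F6	2	II	NOR
PPARA	2	I	NHR
HNF4A	2	II	NHR
ESRRA	2	III	NOR
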