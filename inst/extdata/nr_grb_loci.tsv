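# The three GRB loci that contain several cluster-1 nuclear receptor genes
# (locus windows overlap and share HCNEs within +/-2 Mb).
locus_id	gene
L01	THRB
L01	RARB
L01	NR1D2
L02	THRA
L02	RARA
L02	NR1D1
L03	NR6A1
L03	NR5A1
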