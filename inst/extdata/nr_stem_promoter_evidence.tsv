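# Stem-cell-line (H1-type) promoter evidence for the multi-gene GRB locus
# members: bivalent promoter status (RARB's is weak but present) and
# stem-line expression where decisive (NR6A1 highly expressed, NR5A1 shut
# down); NA where the evidence was not stated.
gene	bivalent	expressed_in_stem
THRB	FALSE	NA
RARB	TRUE	NA
NR1D2	FALSE	NA
THRA	FALSE	TRUE
RARA	TRUE	TRUE
NR1D1	TRUE	TRUE
NR6A1	FALSE	TRUE
NR5A1	FALSE	FALSE
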