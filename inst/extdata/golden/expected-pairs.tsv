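compound_id	protein_id	label	representative_value_uM	provenance
C1	P1	positive	5	dbA;dbB
C4	P1	positive	4	dbA
C5	P1	positive	10	dbA
C6	P1	negative	15	dbA;dbB
C7	P1	negative	12	dbA
C1	P2	positive	20	dbA;dbC
C4	P2	positive	6	dbA
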