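compound_id	protein_id	assay_type	value	unit	label	source
C1	P1	IC50	5	uM	NA	dbA
C1	P1	IC50	8	uM	NA	dbB
C2	P1	IC50	2	uM	NA	dbA
C3	P1	IC50	3	uM	NA	dbA
C4	P1	IC50	4	uM	NA	dbA
C5	P1	IC50	10	uM	NA	dbA
C6	P1	Ki	15	uM	NA	dbA
C6	P1	Ki	20000	nM	NA	dbB
C1	P2	IC50	20	uM	NA	dbA
C1	P2	BINARY	NA	NA	active	dbC
C7	P1	Ki	12	uM	NA	dbA
C4	P2	IC50	6	uM	NA	dbA
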