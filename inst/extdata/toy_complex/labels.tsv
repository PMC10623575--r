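chain	resid	resname	label	segment
A	1	GLY	R1	receptor
A	2	GLY	R2	receptor
A	3	GLY	R3	receptor
A	4	GLY	R4	receptor
A	5	GLY	R5	receptor
A	6	GLY	R6	receptor
A	7	GLY	R7	receptor
A	8	GLY	R8	receptor
L	9	LIG	LIG	ligand
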