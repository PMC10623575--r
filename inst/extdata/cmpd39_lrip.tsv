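# LRIP hotspots of antagonist compound 39 on inactive CB2 (kcal/mol).
residue_label	energy	quantified
L17	-1.24	TRUE
W6.48	-1.31	TRUE
V6.51	-0.78	TRUE
C7.42	-1.52	TRUE
F183	-1.12	TRUE
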