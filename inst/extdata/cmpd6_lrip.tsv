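# LRIP hotspots of agonist compound 6 on active CB2 (kcal/mol).
# F2.61 and F2.64 are named hotspots without a published energy value.
residue_label	energy	quantified
F183	-2.16	TRUE
W5.43	-1.35	TRUE
I186	-0.50	TRUE
F2.61	NA	FALSE
F2.64	NA	FALSE
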