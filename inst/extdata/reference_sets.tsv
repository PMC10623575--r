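# Reference ligands used to build the four receptor-state signatures.
receptor_state	compound_id
CB1_active	AM-4030
CB1_active	AM-11542
CB1_active	THC
CB1_active	WIN-55,212-2
CB2_active	THC
CB2_active	AM-4030
CB2_active	WIN-55,212-2
CB2_active	UR-144
CB1_inactive	SR-147778
CB1_inactive	AM-251
CB1_inactive	MK-0364
CB1_inactive	THC
CB2_inactive	AM-10257
CB2_inactive	AM-630
CB2_inactive	THC
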