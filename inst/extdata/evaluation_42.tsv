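# 42-compound prediction/assay outcome summary (count-faithful).
# Category counts: 26 predicted AGONIST (16 truth AGONIST, 1 truth
# ANTAGONIST, 9 truth INACTIVE); 16 predicted NON_AGONIST (3 truth
# ANTAGONIST, 10 truth INACTIVE, 3 truth AGONIST).  Rows whose compound
# identity is not recoverable from the published text carry synthetic ids
# (provenance = synthetic).
compound_id	predicted	truth	provenance
cmpd6	AGONIST	AGONIST	paper
cmpd8	AGONIST	AGONIST	paper
syn_ag03	AGONIST	AGONIST	synthetic
syn_ag04	AGONIST	AGONIST	synthetic
syn_ag05	AGONIST	AGONIST	synthetic
syn_ag06	AGONIST	AGONIST	synthetic
syn_ag07	AGONIST	AGONIST	synthetic
syn_ag08	AGONIST	AGONIST	synthetic
syn_ag09	AGONIST	AGONIST	synthetic
syn_ag10	AGONIST	AGONIST	synthetic
syn_ag11	AGONIST	AGONIST	synthetic
syn_ag12	AGONIST	AGONIST	synthetic
syn_ag13	AGONIST	AGONIST	synthetic
syn_ag14	AGONIST	AGONIST	synthetic
syn_ag15	AGONIST	AGONIST	synthetic
syn_ag16	AGONIST	AGONIST	synthetic
cmpd38	AGONIST	ANTAGONIST	paper
syn_fp01	AGONIST	INACTIVE	synthetic
syn_fp02	AGONIST	INACTIVE	synthetic
syn_fp03	AGONIST	INACTIVE	synthetic
syn_fp04	AGONIST	INACTIVE	synthetic
syn_fp05	AGONIST	INACTIVE	synthetic
syn_fp06	AGONIST	INACTIVE	synthetic
syn_fp07	AGONIST	INACTIVE	synthetic
syn_fp08	AGONIST	INACTIVE	synthetic
syn_fp09	AGONIST	INACTIVE	synthetic
cmpd39	NON_AGONIST	ANTAGONIST	paper
cmpd40	NON_AGONIST	ANTAGONIST	paper
syn_ant1	NON_AGONIST	ANTAGONIST	synthetic
syn_in01	NON_AGONIST	INACTIVE	synthetic
syn_in02	NON_AGONIST	INACTIVE	synthetic
syn_in03	NON_AGONIST	INACTIVE	synthetic
syn_in04	NON_AGONIST	INACTIVE	synthetic
syn_in05	NON_AGONIST	INACTIVE	synthetic
syn_in06	NON_AGONIST	INACTIVE	synthetic
syn_in07	NON_AGONIST	INACTIVE	synthetic
syn_in08	NON_AGONIST	INACTIVE	synthetic
syn_in09	NON_AGONIST	INACTIVE	synthetic
syn_in10	NON_AGONIST	INACTIVE	synthetic
syn_fn01	NON_AGONIST	AGONIST	synthetic
syn_fn02	NON_AGONIST	AGONIST	synthetic
syn_fn03	NON_AGONIST	AGONIST	synthetic
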