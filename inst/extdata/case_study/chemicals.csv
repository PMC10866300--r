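"id","name","smiles","mw","bp_c","vp_mmhg_25c","wsol_mg_l","logkow","mw_src","bp_c_src","vp_mmhg_25c_src","wsol_mg_l_src","logkow_src"
"p_cymene","p-cymene","CC(C)c1ccc(C)cc1",134.2,176.8,1.55,23.4,4.10,"database","database","database","database","database"
"cumene","cumene","CC(C)c1ccccc1",120.2,152.4,4.6,50,3.66,"database","database","database","database","database"
"dipb_14","1,4-diisopropylbenzene","CC(C)c1ccc(C(C)C)cc1",162.27,210.3,0.24,NA,NA,"database","database","database",NA,NA
"tipb_135","1,3,5-triisopropylbenzene","CC(C)c1cc(C(C)C)cc(C(C)C)c1",204.35,232,0.02,NA,NA,"database","database","database",NA,NA
"benzene","benzene","c1ccccc1",NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"toluene","toluene","Cc1ccccc1",NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"propylene","propylene","C=CC",NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
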