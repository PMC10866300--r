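"process_id","chemical_id","role"
"cumene_process","benzene","reactant"
"cumene_process","propylene","reactant"
"cumene_process","cumene","product"
"p_cymene_process","toluene","reactant"
"p_cymene_process","propylene","reactant"
"p_cymene_process","p_cymene","product"
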