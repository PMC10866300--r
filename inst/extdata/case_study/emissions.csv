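"process_id","species_id","medium","kg_per_kg_product","basis"
"cumene_process","benzene","air",5.9e-06,"measured"
"cumene_process","propylene","air",7.8e-06,"measured"
"cumene_process","cumene","air",1.9e-05,"measured"
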