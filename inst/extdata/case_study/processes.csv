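"process_id","product_id","catalyst_class","temperature_c","time_h","controls","production_volume"
"cumene_process","cumene","solid_acid",NA,NA,"",NA
"p_cymene_process","p_cymene","solid_acid",NA,NA,"",NA
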