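# Controlled vocabularies shared across modules (loaded first).

.property_names <- c("mw", "bp_c", "vp_mmhg_25c", "wsol_mg_l", "logkow")
.log_properties <- c("vp_mmhg_25c", "wsol_mg_l")
.provenance_levels <- c("measured", "database", "estimated", "trend_filled")

.roles <- c("reactant", "solvent", "catalyst", "auxiliary", "product")
.catalyst_classes <- c("solid_acid", "liquid_acid", "base", "metal",
                       "enzyme", "none", "other")
.media <- c("air", "water", "land")
.bases <- c("measured", "estimated", "read_across")
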