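# Shared fixtures, built in code.

smi <- list(
  p_cymene = "CC(C)c1ccc(C)cc1",
  cumene = "CC(C)c1ccccc1",
  dipb_14 = "CC(C)c1ccc(C(C)C)cc1",
  tipb_135 = "CC(C)c1cc(C(C)C)cc(C(C)C)c1",
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  propylene = "C=CC",
  methane = "C"
)

chem_table <- function(ids, extra_props = list()) {
  df <- data.frame(
    id = ids, name = ids,
    smiles = unlist(smi[ids], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  for (p in property_names()) {
    df[[p]] <- NA_real_
    df[[paste0(p, "_src")]] <- NA_character_
  }
  for (p in names(extra_props)) {
    df[[p]] <- extra_props[[p]]
    df[[paste0(p, "_src")]] <- ifelse(is.na(extra_props[[p]]),
                                      NA_character_, "database")
  }
  df
}

# methyl esters of n-alkanoic acids: total carbon count n >= 3
methyl_ester <- function(n) paste0(strrep("C", n - 2), "C(=O)OC")

simple_process <- function(process_id, product_id, reactants = character(0),
                           catalyst = "solid_acid", ...) {
  process_record(
    process_id = process_id, product_id = product_id,
    participants = data.frame(
      chemical_id = c(reactants, product_id),
      role = c(rep("reactant", length(reactants)), "product"),
      stringsAsFactors = FALSE
    ),
    catalyst_class = catalyst, ...
  )
}

emission_row <- function(process_id, species_id, value, medium = "air",
                         basis = "measured") {
  data.frame(process_id = process_id, species_id = species_id,
             medium = medium, kg_per_kg_product = value, basis = basis,
             stringsAsFactors = FALSE)
}
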