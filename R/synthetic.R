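# Synthetic homologous series with known property and emission laws.
#
# The generator emulates the regular patterns a chemical category is
# expected to show: an n-alkylbenzene scaffold grown one methylene at a
# time, physicochemical properties that follow stated linear or
# log10-linear laws in the carbon count, and per-role process emissions
# that follow a log10-linear law with optional multiplicative log-normal
# noise (emissions are positive and span decades, so noise is applied on
# the log scale). The generating laws are returned alongside the data, so
# recovery tests can compare fitted trends against the truth.

#' Specification of a synthetic homologous series
#'
#' Defaults describe an n-alkylbenzene series: vapour pressure falling half
#' a decade per carbon, boiling point rising about 25 degrees C per carbon,
#' logKow rising half a unit per carbon, water solubility falling about
#' 0.65 decades per carbon, and a product-role air emission falling 0.1
#' decades per carbon from a 1e-4 kg/kg baseline.
#'
#' @param carbon_range Integer vector of total carbon counts (at least 3
#'   members); each must be at least the template's own carbon count.
#' @param template Scaffold SMILES with a `{chain}` placeholder where the
#'   alkyl chain is grafted.
#' @param property_laws Named list per property:
#'   `list(intercept=, slope=, domain="linear"|"log10")`, evaluated at the
#'   carbon count.
#' @param emission_laws Named list per participant role, same shape;
#'   emissions are always generated in log10 domain.
#' @param noise_sd Standard deviation of the log10-domain emission noise
#'   (0 gives exact laws).
#' @param seed Integer seed; generation is reproducible for a fixed seed.
#' @return A `series_spec` list.
#' @export
series_spec <- function(carbon_range = 7:12,
                        template = "{chain}c1ccccc1",
                        property_laws = list(
                          bp_c = list(intercept = -64, slope = 25,
                                      domain = "linear"),
                          vp_mmhg_25c = list(intercept = 3, slope = -0.5,
                                             domain = "log10"),
                          wsol_mg_l = list(intercept = 7.27, slope = -0.65,
                                           domain = "log10"),
                          logkow = list(intercept = -0.77, slope = 0.5,
                                        domain = "linear")
                        ),
                        emission_laws = list(
                          product = list(intercept = -4, slope = -0.1,
                                         domain = "log10")
                        ),
                        noise_sd = 0, seed) {
  stopifnot(length(carbon_range) >= 3L, noise_sd >= 0,
            !missing(seed), is.numeric(seed))
  base_carbons <- parse_structure(sub("{chain}", "", template,
                                      fixed = TRUE))$carbon_count
  if (any(carbon_range < base_carbons)) {
    stop("template holds ", base_carbons, " carbons; cannot build a member ",
         "with ", min(carbon_range), call. = FALSE)
  }
  bad_role <- setdiff(names(emission_laws), .roles)
  if (length(bad_role)) {
    stop("emission law for unknown role(s): ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  structure(
    list(carbon_range = sort(unique(as.integer(carbon_range))),
         template = template, base_carbons = base_carbons,
         property_laws = property_laws, emission_laws = emission_laws,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "series_spec"
  )
}

.eval_law <- function(law, n) {
  y <- law$intercept + law$slope * n
  if (identical(law$domain, "log10")) 10^y else y
}

#' Generate a synthetic homologous category
#'
#' Builds the member structures from the scaffold template, evaluates the
#' property and emission laws at each member's carbon count, adds seeded
#' log-normal noise to the emissions, and assembles the standard record
#' tables plus one manufacturing process per member (solid-acid alkylation
#' of benzene, mirroring the case-study chemistry).
#'
#' @param spec A [series_spec()].
#' @return List `chemicals`, `processes`, `participants`, `emissions`,
#'   and `truth` — the noise-free law values per member and role.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  ns <- spec$carbon_range
  ids <- sprintf("c%02d", ns)
  smiles <- vapply(ns, function(n) {
    sub("{chain}", strrep("C", n - spec$base_carbons), spec$template,
        fixed = TRUE)
  }, character(1))

  chemicals <- data.frame(
    id = ids, name = sprintf("series member C%d", ns), smiles = smiles,
    stringsAsFactors = FALSE
  )
  for (p in .property_names) {
    law <- spec$property_laws[[p]]
    chemicals[[p]] <- if (!is.null(law)) .eval_law(law, ns) else NA_real_
    chemicals[[paste0(p, "_src")]] <-
      ifelse(is.na(chemicals[[p]]), NA_character_, "database")
  }
  if (is.null(spec$property_laws$mw)) {
    chemicals$mw <- vapply(smiles, function(sm) {
      molecular_weight(parse_structure(sm))
    }, numeric(1), USE.NAMES = FALSE)
    chemicals$mw_src <- "estimated"
  }

  need_reactant <- any(names(spec$emission_laws) %in%
                         setdiff(.roles, "product"))
  aux <- data.frame(
    id = c("benzene_feed", if (need_reactant) "alkene_feed"),
    name = c("benzene feedstock", if (need_reactant) "alkene feedstock"),
    smiles = c("c1ccccc1", if (need_reactant) "C=C"),
    stringsAsFactors = FALSE
  )
  for (p in .property_names) {
    aux[[p]] <- NA_real_
    aux[[paste0(p, "_src")]] <- NA_character_
  }
  chemicals <- rbind(chemicals, aux)[, .chem_columns]

  processes <- list()
  emission_rows <- list()
  truth_rows <- list()
  for (i in seq_along(ns)) {
    pid <- sprintf("proc_%s", ids[i])
    part <- data.frame(
      chemical_id = c("benzene_feed",
                      if (need_reactant) "alkene_feed", ids[i]),
      role = c("reactant", if (need_reactant) "reactant", "product"),
      stringsAsFactors = FALSE
    )
    processes[[pid]] <- process_record(
      process_id = pid, product_id = ids[i], participants = part,
      catalyst_class = "solid_acid", temperature_c = 250, time_h = 2
    )
    for (role in names(spec$emission_laws)) {
      law <- spec$emission_laws[[role]]
      species <- switch(role, product = ids[i], "alkene_feed")
      log_true <- law$intercept + law$slope * ns[i]
      value <- 10^(log_true + stats::rnorm(1, 0, spec$noise_sd))
      emission_rows[[length(emission_rows) + 1L]] <- data.frame(
        process_id = pid, species_id = species, medium = "air",
        kg_per_kg_product = value, basis = "measured",
        stringsAsFactors = FALSE
      )
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        member_id = ids[i], carbon_count = ns[i], role = role,
        species_id = species, log10_value = log_true, value = 10^log_true,
        intercept = law$intercept, slope = law$slope,
        stringsAsFactors = FALSE
      )
    }
  }
  participants <- do.call(rbind, lapply(processes, function(p) {
    data.frame(process_id = p$process_id,
               chemical_id = p$participants$chemical_id,
               role = p$participants$role, stringsAsFactors = FALSE)
  }))
  rownames(participants) <- NULL
  list(
    chemicals = chemicals,
    processes = processes,
    participants = participants,
    emissions = do.call(rbind, emission_rows),
    truth = do.call(rbind, truth_rows),
    spec = spec
  )
}
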