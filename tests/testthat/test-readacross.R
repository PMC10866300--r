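case_props <- function() {
  cs <- load_case_study()
  cs$chemicals
}

test_that("read-across factors are target over source", {
  chems <- case_props()
  t <- chems[chems$id == "p_cymene", ]
  s <- chems[chems$id == "cumene", ]
  f <- compute_factors(t, s, c("mw", "vp_mmhg_25c"))
  expect_equal(f$factor[f$property == "mw"], 134.2 / 120.2,
               tolerance = 1e-12)
  expect_equal(round(f$factor[f$property == "mw"], 4), 1.1165)
  expect_equal(round(f$factor[f$property == "vp_mmhg_25c"], 4), 0.337)
  expect_equal(compute_factors(t, t, "mw")$factor, 1)
  expect_error(compute_factors(t, s, "density"), "lacks property")
  s$vp_mmhg_25c <- 0
  expect_error(compute_factors(t, s, "vp_mmhg_25c"), "zero")
})

test_that("factor combination rules behave as documented", {
  expect_equal(overall_factor(c(1, 1)), 1)
  expect_equal(overall_factor(c(2, 0.5)), 1)          # geometric mean
  expect_equal(overall_factor(c(2, 0.5), "product"), 1)
  expect_equal(overall_factor(c(2, 8)), 4)
  expect_equal(overall_factor(c(2, 8), "unity"), 1)
  expect_error(overall_factor(c(2, -1)), "positive")
})

closest_setup <- function(factor = 1) {
  cs <- load_case_study()
  rm <- map_species_roles(cs$processes$p_cymene_process,
                          cs$processes$cumene_process, cs$chemicals)
  estimate_closest(cs$processes$p_cymene_process,
                   cs$processes$cumene_process, rm, cs$emissions,
                   factor = factor)
}

test_that("closest-analogue mode relabels and scales the source rows", {
  est <- closest_setup(factor = 1)$estimates
  tab <- estimates_table(est)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$kg_per_kg_product[tab$species_id == "toluene"], 5.9e-06)
  expect_equal(tab$kg_per_kg_product[tab$species_id == "propylene"],
               7.8e-06)
  expect_equal(tab$kg_per_kg_product[tab$species_id == "p_cymene"], 1.9e-05)
  expect_true(all(tab$basis == "read_across"))

  half <- estimates_table(closest_setup(factor = 0.5)$estimates)
  expect_equal(half$kg_per_kg_product[half$species_id == "p_cymene"],
               1.9e-05 * 0.5)
})

test_that("self-read-across returns the measured values exactly", {
  cs <- load_case_study()
  p <- cs$processes$cumene_process
  rm <- map_species_roles(p, p, cs$chemicals)
  est <- estimate_closest(p, p, rm, cs$emissions, factor = 1)$estimates
  tab <- estimates_table(est)
  src <- cs$emissions[match(tab$species_id, cs$emissions$species_id), ]
  expect_identical(tab$kg_per_kg_product, src$kg_per_kg_product)
})

test_that("estimates scale equivariantly with the source emissions", {
  cs <- load_case_study()
  rm <- map_species_roles(cs$processes$p_cymene_process,
                          cs$processes$cumene_process, cs$chemicals)
  base <- estimates_table(
    estimate_closest(cs$processes$p_cymene_process,
                     cs$processes$cumene_process, rm, cs$emissions)$estimates)
  for (k in c(0.1, 3, 1e4)) {
    em <- cs$emissions
    em$kg_per_kg_product <- em$kg_per_kg_product * k
    scaled <- estimates_table(
      estimate_closest(cs$processes$p_cymene_process,
                       cs$processes$cumene_process, rm, em)$estimates)
    expect_equal(scaled$kg_per_kg_product, base$kg_per_kg_product * k,
                 tolerance = 1e-12)
  }
})

test_that("the optional molar basis scales rows by the weight ratio", {
  cs <- load_case_study()
  rm <- map_species_roles(cs$processes$p_cymene_process,
                          cs$processes$cumene_process, cs$chemicals)
  tab <- estimates_table(
    estimate_closest(cs$processes$p_cymene_process,
                     cs$processes$cumene_process, rm, cs$emissions,
                     molar_basis = TRUE,
                     chemicals = cs$chemicals)$estimates)
  ratio <- molecular_weight(parse_structure(smi$p_cymene)) /
    molecular_weight(parse_structure(smi$cumene))
  expect_equal(tab$kg_per_kg_product[tab$species_id == "p_cymene"],
               1.9e-05 * ratio, tolerance = 1e-12)
  # propylene maps onto itself, so the molar correction is a no-op there
  expect_equal(tab$kg_per_kg_product[tab$species_id == "propylene"],
               7.8e-06, tolerance = 1e-12)
})

test_that("unmatched source species are dropped with a warning entry", {
  chems <- chem_table(c("cumene", "p_cymene", "benzene", "toluene",
                        "propylene"))
  src <- process_record(
    "src", "cumene",
    data.frame(chemical_id = c("benzene", "propylene", "cumene"),
               role = c("solvent", "reactant", "product")),
    catalyst_class = "solid_acid")
  tgt <- simple_process("tgt", "p_cymene",
                        reactants = c("toluene", "propylene"))
  rm <- map_species_roles(tgt, src, chems)
  em <- rbind(emission_row("src", "benzene", 5.9e-06),
              emission_row("src", "propylene", 7.8e-06),
              emission_row("src", "cumene", 1.9e-05))
  res <- estimate_closest(tgt, src, rm, em)
  expect_identical(length(res$estimates), 2L)
  expect_match(res$warnings, "benzene", all = FALSE)
})

test_that("closest mode demands measured source emissions", {
  cs <- load_case_study()
  em <- cs$emissions
  em$basis <- "estimated"
  rm <- map_species_roles(cs$processes$p_cymene_process,
                          cs$processes$cumene_process, cs$chemicals)
  expect_error(
    estimate_closest(cs$processes$p_cymene_process,
                     cs$processes$cumene_process, rm, em),
    "no measured emissions")
})

test_that("averaging and conservative selection follow order statistics", {
  expect_equal(estimate_average(c(2e-06, 4e-06)), 3e-06)
  expect_equal(estimate_conservative(c(2e-06, 4e-06)), 4e-06)
  expect_equal(estimate_average(c(5e-05, 5e-05)), 5e-05)
  expect_equal(estimate_conservative(c(5e-05, 5e-05)), 5e-05)
  expect_error(estimate_average(1e-06), ">= 2")
  expect_error(estimate_conservative(1e-06), ">= 2")
  set.seed(3)
  for (i in 1:25) {
    v <- stats::rlnorm(sample(2:8, 1), meanlog = -12)
    expect_gte(estimate_conservative(v), estimate_average(v))
    expect_gte(estimate_average(v), min(v))
  }
})

test_that("a zero-noise log-linear category is recovered by the trend", {
  ser <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0,
                                     seed = 5))
  target_id <- "c10"
  tproc <- ser$processes[[sprintf("proc_%s", target_id)]]
  srcs <- ser$processes[names(ser$processes) != tproc$process_id]
  em <- ser$emissions[ser$emissions$process_id != tproc$process_id, ]
  res <- estimate_trend(unname(srcs), em, tproc, ser$chemicals)
  est <- res$estimates[[1]]
  expect_identical(est$species_id, target_id)
  truth <- 10^(-4 - 0.1 * 10)
  expect_lt(abs(est$value - truth) / truth, 1e-9)
  expect_false(est$extrapolated)
})

test_that("withholding any member reproduces its generated emission", {
  ser <- generate_series(series_spec(carbon_range = 8:12, noise_sd = 0,
                                     seed = 5))
  for (target_id in ser$truth$member_id) {
    tproc <- ser$processes[[sprintf("proc_%s", target_id)]]
    srcs <- ser$processes[names(ser$processes) != tproc$process_id]
    em <- ser$emissions[ser$emissions$process_id != tproc$process_id, ]
    est <- estimate_trend(unname(srcs), em, tproc,
                          ser$chemicals)$estimates[[1]]
    truth <- ser$truth$value[ser$truth$member_id == target_id]
    expect_lt(abs(est$value - truth) / truth, 1e-9)
  }
})

test_that("a flat trend returns the shared value and extremes are flagged", {
  ser <- generate_series(series_spec(
    carbon_range = 8:10,
    emission_laws = list(product = list(intercept = -5, slope = 0,
                                        domain = "log10")),
    noise_sd = 0, seed = 2))
  tproc <- ser$processes$proc_c09
  srcs <- ser$processes[c("proc_c08", "proc_c10")]
  em <- ser$emissions[ser$emissions$process_id != "proc_c09", ]
  est <- estimate_trend(unname(srcs), em, tproc, ser$chemicals)$estimates[[1]]
  expect_equal(est$value, 1e-05, tolerance = 1e-12)

  # target beyond the top of the series: flagged extrapolation
  ser2 <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0,
                                      seed = 2))
  tproc2 <- ser2$processes$proc_c12
  srcs2 <- ser2$processes[!names(ser2$processes) %in% "proc_c12"]
  em2 <- ser2$emissions[ser2$emissions$process_id != "proc_c12", ]
  est2 <- estimate_trend(unname(srcs2), em2, tproc2,
                         ser2$chemicals)$estimates[[1]]
  expect_true(est2$extrapolated)
})

test_that("every estimate re-derives bit-exactly from its provenance", {
  # closest
  for (e in closest_setup(factor = 0.337)$estimates) {
    expect_true(audit_estimate(e)$consistent)
  }
  # trend
  ser <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0.2,
                                     seed = 9))
  tproc <- ser$processes$proc_c10
  srcs <- ser$processes[names(ser$processes) != "proc_c10"]
  em <- ser$emissions[ser$emissions$process_id != "proc_c10", ]
  for (e in estimate_trend(unname(srcs), em, tproc,
                           ser$chemicals)$estimates) {
    expect_true(audit_estimate(e)$consistent)
  }
  # pooled average / conservative
  for (mode in c("average", "conservative")) {
    res <- emitra:::.estimate_pooled(mode, unname(srcs), em, tproc,
                                     ser$chemicals)
    for (e in res$estimates) expect_true(audit_estimate(e)$consistent)
  }
})
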