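test_that("the one-to-one case study reproduces the worked example", {
  cs <- load_case_study()
  rep <- run_framework(c(cs, list(mode = "closest", factor_rule = "unity")))
  expect_false(rep$halted)
  expect_identical(rep$grouping, "one_to_one")
  expect_identical(rep$analogues$source_id[1], "cumene")
  expect_identical(rep$overall_factor, 1)
  m <- rep$role_map$map
  expect_identical(m$target_id[m$source_id == "benzene"], "toluene")
  tab <- estimates_table(rep$estimates)
  expect_identical(sort(tab$species_id),
                   c("p_cymene", "propylene", "toluene"))
  expect_true(all(tab$uncertainty == "low"))
  grades <- vapply(rep$estimates, function(e) e$uncertainty$grade,
                   character(1))
  expect_true(all(grades == "low"))
})

test_that("a target identical to a source reads across as the identity", {
  cs <- load_case_study()
  chems <- cs$chemicals
  twin <- chems[chems$id == "cumene", ]
  twin$id <- "cumene_twin"
  chems <- rbind(chems, twin)
  procs <- cs$processes
  procs$twin_process <- process_record(
    "twin_process", "cumene_twin",
    data.frame(chemical_id = c("benzene", "propylene", "cumene_twin"),
               role = c("reactant", "reactant", "product")),
    catalyst_class = "solid_acid")
  rep <- run_framework(list(
    chemicals = chems, processes = procs, emissions = cs$emissions,
    target_id = "cumene_twin", target_process_id = "twin_process",
    mode = "closest", factor_rule = "geomean",
    factor_properties = "vp_mmhg_25c"))
  expect_false(rep$halted)
  expect_equal(rep$analogues$similarity[1], 1)
  expect_identical(rep$overall_factor, 1)
  tab <- estimates_table(rep$estimates)
  src <- cs$emissions[match(c("benzene", "propylene", "cumene"),
                            cs$emissions$species_id), ]
  expect_identical(
    tab$kg_per_kg_product[match(c("benzene", "propylene", "cumene_twin"),
                                tab$species_id)],
    src$kg_per_kg_product)
})

test_that("a catalyst mismatch halts the run at process comparison", {
  cs <- load_case_study()
  procs <- cs$processes
  liquid <- procs$cumene_process
  liquid$catalyst_class <- "liquid_acid"
  procs$cumene_process <- liquid
  rep <- run_framework(c(list(chemicals = cs$chemicals, processes = procs,
                              emissions = cs$emissions,
                              target_id = "p_cymene",
                              mode = "closest", factor_rule = "unity")))
  expect_true(rep$halted)
  last <- rep$steps[[length(rep$steps)]]
  expect_identical(last$step, 5)
  expect_match(rep$halt_reason, "catalyst")
})

test_that("a run with no analogue above the cutoff halts at selection", {
  cs <- load_case_study()
  rep <- run_framework(c(cs, list(cutoff = 0.99, mode = "closest")))
  expect_true(rep$halted)
  expect_identical(rep$steps[[length(rep$steps)]]$step, 3)
})

test_that("auto mode prefers the category trend when two sources exist", {
  ser <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0,
                                     seed = 13))
  rep <- run_framework(list(
    chemicals = ser$chemicals, processes = ser$processes,
    emissions = ser$emissions[ser$emissions$process_id != "proc_c10", ],
    target_id = "c10", target_process_id = "proc_c10", mode = "auto"))
  expect_false(rep$halted)
  expect_identical(rep$mode, "trend")
  expect_identical(rep$grouping, "many_to_one")
  est <- rep$estimates[[1]]
  truth <- 10^(-4 - 0.1 * 10)
  expect_lt(abs(est$value - truth) / truth, 1e-9)
})

test_that("pooled modes respect dominance through the framework", {
  ser <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0.4,
                                     seed = 21))
  em <- ser$emissions[ser$emissions$process_id != "proc_c10", ]
  base <- list(chemicals = ser$chemicals, processes = ser$processes,
               emissions = em, target_id = "c10",
               target_process_id = "proc_c10")
  avg <- run_framework(c(base, list(mode = "average")))
  con <- run_framework(c(base, list(mode = "conservative")))
  expect_false(avg$halted)
  expect_false(con$halted)
  expect_gte(con$estimates[[1]]$value, avg$estimates[[1]]$value)
})

test_that("gap filling triggers a second estimation pass", {
  ser <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0,
                                     seed = 31))
  chems <- ser$chemicals
  em <- ser$emissions[ser$emissions$process_id != "proc_c10", ]
  base <- list(chemicals = chems, processes = ser$processes,
               emissions = em, target_id = "c10",
               target_process_id = "proc_c10", mode = "closest",
               factor_rule = "geomean", factor_properties = "vp_mmhg_25c")
  first <- run_framework(base)
  chosen <- first$analogues$source_id[1]

  # withhold the chosen source's vapour pressure: the first pass cannot
  # compute the factor, the trend fill supplies it on iteration two
  chems2 <- chems
  chems2$vp_mmhg_25c[chems2$id == chosen] <- NA
  chems2$vp_mmhg_25c_src[chems2$id == chosen] <- NA
  base$chemicals <- chems2
  rep <- run_framework(base)
  expect_false(rep$halted)
  expect_identical(rep$iterations, 2L)
  # fill is exact on the noise-free law, so the factor matches the original
  expect_equal(rep$overall_factor, first$overall_factor, tolerance = 1e-9)
  grades <- vapply(rep$estimates, function(e) e$uncertainty$grade,
                   character(1))
  expect_true(all(grades != "low"))  # trend-filled factor input
})
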