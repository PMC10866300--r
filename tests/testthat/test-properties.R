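test_that("gap analysis reports the tabulated logKow gaps", {
  cs <- load_case_study()
  four <- cs$chemicals[cs$chemicals$id %in%
                         c("p_cymene", "cumene", "dipb_14", "tipb_135"), ]
  rep <- gap_analysis(four, required = "logkow")
  expect_identical(sort(rep$missing$id), c("dipb_14", "tipb_135"))
  expect_identical(rep$n_missing, 2L)

  full <- gap_analysis(four)
  expect_true(all(full$present[, c("mw", "bp_c", "vp_mmhg_25c")]))
})

test_that("gap analysis handles complete and empty property sets", {
  df <- chem_table("cumene",
                   extra_props = stats::setNames(
                     as.list(c(120.2, 152.4, 4.6, 50, 3.66)),
                     property_names()))
  rep <- gap_analysis(df)
  expect_identical(rep$n_missing, 0L)
  empty <- gap_analysis(df, required = character(0))
  expect_identical(empty$n_cells, 0L)
  expect_error(gap_analysis(df, required = "density"), "unknown property")
})

test_that("a collinear linear trend interpolates exactly", {
  # bp exactly linear in carbon count over methyl esters C4, C6, C8
  members <- data.frame(
    id = c("e4", "e6", "e8", "e5"),
    smiles = vapply(c(4, 6, 8, 5), methyl_ester, character(1)),
    stringsAsFactors = FALSE
  )
  for (p in property_names()) {
    members[[p]] <- NA_real_
    members[[paste0(p, "_src")]] <- NA_character_
  }
  members$bp_c <- c(10 + 12 * 4, 10 + 12 * 6, 10 + 12 * 8, NA)
  fill <- fill_by_trend(members$id, members, "bp_c", "e5")
  expect_equal(fill$value, 10 + 12 * 5, tolerance = 1e-12)
  expect_false(fill$extrapolated)
  expect_identical(fill$provenance, "trend_filled")
})

test_that("a log-linear vapour pressure law is recovered at the target", {
  ser <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0,
                                     seed = 1))
  chems <- ser$chemicals
  target <- "c10"
  chems$vp_mmhg_25c[chems$id == target] <- NA
  members <- chems$id[grepl("^c", chems$id)]
  fill <- fill_by_trend(members, chems, "vp_mmhg_25c", target)
  expect_equal(fill$value, 10^(3 - 0.5 * 10), tolerance = 1e-9)
  expect_false(fill$extrapolated)
  expect_identical(fill$fit$domain, "log10")
})

test_that("targets outside the member range are flagged as extrapolated", {
  ser <- generate_series(series_spec(carbon_range = 7:12, noise_sd = 0,
                                     seed = 1))
  chems <- ser$chemicals
  chems$vp_mmhg_25c[chems$id == "c12"] <- NA
  fill <- fill_by_trend(chems$id[grepl("^c", chems$id)], chems,
                        "vp_mmhg_25c", "c12")
  expect_true(fill$extrapolated)
  expect_equal(fill$value, 10^(3 - 0.5 * 12), tolerance = 1e-9)
})

test_that("trend filling refuses thin data and present values", {
  df <- chem_table(c("cumene", "p_cymene", "dipb_14"))
  df$logkow <- c(3.66, NA, NA)
  expect_error(fill_by_trend(df$id, df, "logkow", "p_cymene"),
               "requires >= 2 members")
  df$logkow <- c(3.66, 4.10, 2.0)
  expect_error(fill_by_trend(df$id, df, "logkow", "p_cymene"),
               "already has a value")
})

test_that("fills never overwrite measured or database values", {
  df <- chem_table(c("cumene", "p_cymene"),
                   extra_props = list(logkow = c(3.66, 4.10)))
  fake_fill <- structure(
    list(property = "logkow", target_id = "p_cymene", value = -99,
         provenance = "trend_filled", extrapolated = FALSE),
    class = "trend_fill")
  out <- emitra:::.apply_fills(df, list(fake_fill))
  expect_identical(out$chemicals$logkow, df$logkow)
  expect_identical(length(out$applied), 0L)
})
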