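alkyl_library <- function() {
  chem_table(c("cumene", "dipb_14", "tipb_135", "methane"))
}

test_that("cumene is retrieved as the closest analogue of p-cymene", {
  target <- chem_table("p_cymene")
  res <- find_analogues(target, alkyl_library(), cutoff = 0)
  expect_identical(res$source_id[res$rank == 1], "cumene")
  expect_identical(res$rank, seq_len(nrow(res)))
  expect_true(all(diff(res$similarity) <= 0))
})

test_that("a structural duplicate under another id scores exactly 1", {
  target <- chem_table("cumene")
  lib <- data.frame(id = "cumene_copy", name = "copy",
                    smiles = "CC(C)c1ccccc1", stringsAsFactors = FALSE)
  res <- find_analogues(target, lib, cutoff = 0)
  expect_identical(res$similarity, 1)
})

test_that("cutoff 1 with no identical member returns an empty list", {
  res <- find_analogues(chem_table("p_cymene"), alkyl_library(), cutoff = 1)
  expect_identical(nrow(res), 0L)
})

test_that("raising the cutoff never adds matches", {
  target <- chem_table("p_cymene")
  lib <- alkyl_library()
  prev <- find_analogues(target, lib, cutoff = 0)$source_id
  for (cut in c(0.2, 0.4, 0.6, 0.9)) {
    cur <- find_analogues(target, lib, cutoff = cut)$source_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("ranking is invariant under library permutation", {
  target <- chem_table("p_cymene")
  lib <- alkyl_library()
  ref <- find_analogues(target, lib, cutoff = 0)
  set.seed(7)
  for (i in 1:5) {
    shuffled <- lib[sample(nrow(lib)), , drop = FALSE]
    rownames(shuffled) <- NULL
    expect_identical(find_analogues(target, shuffled, cutoff = 0), ref)
  }
})

test_that("the target is excluded and an empty library is an error", {
  lib <- chem_table(c("p_cymene", "cumene"))
  res <- find_analogues(chem_table("p_cymene"), lib, cutoff = 0)
  expect_false("p_cymene" %in% res$source_id)
  expect_error(find_analogues(chem_table("p_cymene"), lib[0, ]), "empty")
  expect_error(
    find_analogues(chem_table("p_cymene"), chem_table("p_cymene")), "empty")
})

test_that("grouping mode follows the target/source counts", {
  expect_identical(select_mode(1, 1), "one_to_one")
  expect_identical(select_mode(2, 1), "one_to_many")
  expect_identical(select_mode(1, 3), "many_to_one")
  expect_identical(select_mode(4, 2), "many_to_many")
  expect_error(select_mode(0, 1), "at least 1")
})

test_that("functional groups are detected from the pattern dictionary", {
  expect_identical(detect_functional_groups("CC(C)=O")[["ketone"]], 1L)
  ea <- detect_functional_groups("CCOC(C)=O")
  expect_identical(ea[["ester"]], 1L)
  expect_identical(detect_functional_groups(smi$benzene)[["aromatic_ring"]],
                   1L)
  expect_identical(length(detect_functional_groups(smi$methane)), 0L)
})

test_that("a homologous ester series validates as a category", {
  members <- data.frame(
    id = c("e4", "e6", "e8"),
    smiles = vapply(c(4, 6, 8), methyl_ester, character(1)),
    stringsAsFactors = FALSE
  )
  cat <- validate_category(members)
  expect_identical(cat$member_ids, c("e4", "e6", "e8"))
  expect_true(cat$valid)
  expect_true(all(cat$validation$pass))
  expect_match(cat$shared_feature, "ester")
})

test_that("a 3-carbon jump between adjacent members fails the chain rule", {
  members <- data.frame(
    id = c("e4", "e7"),
    smiles = vapply(c(4, 7), methyl_ester, character(1)),
    stringsAsFactors = FALSE
  )
  cat <- validate_category(members)
  expect_false(cat$valid)
  expect_match(cat$validation$reason[1], "chain length difference > 2")
  expect_true(cat$validation$groups_ok[1])
})

test_that("a ketone inserted into an ester series fails the group rule", {
  members <- data.frame(
    id = c("e4", "k6", "e8"),
    smiles = c(methyl_ester(4), "CCCCC(C)=O", methyl_ester(8)),
    stringsAsFactors = FALSE
  )
  cat <- validate_category(members)
  expect_false(cat$valid)
  expect_true(all(!cat$validation$groups_ok))
  expect_match(cat$validation$reason[1], "functional group mismatch")
})
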