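# Analogue identification and category validation.

# Substructure dictionary for functional-group perception (SMARTS, matched
# by OpenBabel). Counts are compared as multisets when validating a
# homologous category; overlapping definitions (an ester also contains an
# ether oxygen) are harmless because the overlap is consistent across
# members.
.functional_groups <- c(
  carboxylic_acid = "[CX3](=O)[OX2H1]",
  ester           = "[CX3](=O)[OX2H0][#6]",
  aldehyde        = "[CX3H1]=O",
  ketone          = "[#6][CX3](=O)[#6]",
  alcohol         = "[OX2H][CX4]",
  phenol          = "[OX2H][c]",
  ether           = "[OD2]([#6])[#6]",
  amine           = "[NX3;H2,H1;!$(NC=O)]",
  amide           = "[NX3][CX3](=O)",
  nitrile         = "[NX1]#[CX2]",
  thiol           = "[SX2H]",
  alkyl_halide    = "[CX4][F,Cl,Br,I]",
  alkene          = "[CX3]=[CX3]",
  alkyne          = "[CX2]#[CX2]",
  aromatic_ring   = "c1ccccc1"
)

#' Count functional groups present in a structure
#'
#' Matches a fixed dictionary of substructure patterns (acid, ester,
#' aldehyde, ketone, alcohol, amine, aromatic ring, halide, ...) and
#' returns the non-zero match counts. Used to test the "same functional
#' groups" requirement for category membership.
#'
#' @param s An `emitra_structure` or a SMILES string.
#' @return Named integer vector of match counts (non-zero groups only).
#' @export
detect_functional_groups <- function(s) {
  smiles <- if (inherits(s, "emitra_structure")) s$smiles else
    parse_structure(s)$smiles
  mol <- .ob_mol(smiles)
  counts <- vapply(.functional_groups, function(p) {
    as.integer(ChemmineOB::smartsSearch_OB(mol, p, uniqueMatches = TRUE))
  }, integer(1))
  counts[counts > 0L]
}

#' Rank candidate source chemicals by similarity to a target
#'
#' Fingerprints the target and every library member under one scheme and
#' returns the members at or above the similarity cutoff, most similar
#' first. Ties are broken deterministically: smaller absolute molecular
#' weight difference first, then lexicographic id — so the result is
#' invariant under permutation of the library.
#'
#' @param target A SMILES string, an `emitra_structure`, or a single-row
#'   chemicals table (columns `id`, `smiles`).
#' @param library Chemicals table with columns `id` and `smiles`. Any row
#'   whose `id` equals the target's is excluded (a structural duplicate
#'   under a different id is kept and scores 1).
#' @param cutoff Minimum similarity retained, in \[0, 1\]. The default is
#'   calibrated to the counted atom-pair scheme, whose scores run much
#'   lower than substructure-key similarities.
#' @param params Fingerprint scheme, see [fingerprint_params()].
#' @param measured_ids Optional ids of chemicals with measured emission
#'   data, flagged in the result.
#' @return Data frame with columns `target_id`, `source_id`, `similarity`,
#'   `rank` (1..n, no gaps), `has_measured_emissions`.
#' @export
find_analogues <- function(target, library, cutoff = 0.25,
                           params = fingerprint_params(),
                           measured_ids = character(0)) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (is.data.frame(library) && nrow(library) == 0L) {
    stop("analogue library is empty", call. = FALSE)
  }
  stopifnot(is.data.frame(library), all(c("id", "smiles") %in% names(library)))
  tgt <- .as_target(target)
  keep <- library$id != tgt$id
  lib <- library[keep, , drop = FALSE]
  if (nrow(lib) == 0L) stop("analogue library is empty", call. = FALSE)

  tfp <- fingerprint(tgt$structure, params)
  tmw <- molecular_weight(tgt$structure)
  sims <- numeric(nrow(lib))
  dmw <- numeric(nrow(lib))
  for (i in seq_len(nrow(lib))) {
    s <- parse_structure(lib$smiles[i], name = lib$id[i])
    sims[i] <- tanimoto(tfp, fingerprint(s, params))
    dmw[i] <- abs(molecular_weight(s) - tmw)
  }
  res <- data.frame(
    target_id = tgt$id,
    source_id = lib$id,
    similarity = sims,
    dmw = dmw,
    stringsAsFactors = FALSE
  )
  res <- res[res$similarity >= cutoff, , drop = FALSE]
  res <- res[order(-res$similarity, res$dmw, res$source_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$has_measured_emissions <- res$source_id %in% measured_ids
  res$dmw <- NULL
  rownames(res) <- NULL
  res
}

.as_target <- function(target) {
  if (inherits(target, "emitra_structure")) {
    id <- if (!is.na(target$name)) target$name else target$smiles
    return(list(id = id, structure = target))
  }
  if (is.data.frame(target)) {
    stopifnot(nrow(target) == 1L, all(c("id", "smiles") %in% names(target)))
    return(list(id = target$id,
                structure = parse_structure(target$smiles, name = target$id)))
  }
  s <- parse_structure(target)
  list(id = s$smiles, structure = s)
}

#' Validate a chemical category for read-across
#'
#' Orders the members by carbon count and checks, for every adjacent pair,
#' the two structural rules for category membership: identical
#' functional-group multiset and a chain-length difference of at most two
#' carbon atoms. Failures are reported in the validation table, not raised.
#'
#' @param members Chemicals table (columns `id`, `smiles`) with at least
#'   two rows.
#' @param max_carbon_diff Maximum carbon-count difference allowed between
#'   adjacent members (default 2).
#' @return An `emitra_category`: `member_ids` ordered by carbon count,
#'   `carbon_counts`, `shared_feature` (groups common to all members),
#'   `validation` (one row per adjacent pair with `groups_ok`, `chain_ok`,
#'   `pass`, `reason`) and `valid` (all pairs pass).
#' @export
validate_category <- function(members, max_carbon_diff = 2L) {
  stopifnot(is.data.frame(members), all(c("id", "smiles") %in% names(members)),
            nrow(members) >= 2L)
  structs <- lapply(seq_len(nrow(members)), function(i) {
    parse_structure(members$smiles[i], name = members$id[i])
  })
  nc <- vapply(structs, function(s) s$carbon_count, numeric(1))
  ord <- order(nc, members$id)
  structs <- structs[ord]
  ids <- members$id[ord]
  nc <- nc[ord]
  groups <- lapply(structs, detect_functional_groups)

  pair <- function(i) {
    ga <- groups[[i]]; gb <- groups[[i + 1L]]
    groups_ok <- identical(ga[order(names(ga))], gb[order(names(gb))])
    dc <- nc[i + 1L] - nc[i]
    chain_ok <- dc <= max_carbon_diff
    reason <- character(0)
    if (!groups_ok) reason <- c(reason, "functional group mismatch")
    if (!chain_ok) {
      reason <- c(reason,
                  sprintf("chain length difference > %d", max_carbon_diff))
    }
    data.frame(
      member_a = ids[i], member_b = ids[i + 1L], carbon_diff = dc,
      groups_ok = groups_ok, chain_ok = chain_ok,
      pass = groups_ok && chain_ok,
      reason = if (length(reason)) paste(reason, collapse = "; ") else "",
      stringsAsFactors = FALSE
    )
  }
  validation <- do.call(rbind, lapply(seq_len(length(ids) - 1L), pair))
  shared <- Reduce(intersect, lapply(groups, names))
  structure(
    list(
      member_ids = ids,
      carbon_counts = stats::setNames(nc, ids),
      shared_feature = if (length(shared)) paste(shared, collapse = ", ")
                       else "none",
      validation = validation,
      valid = all(validation$pass)
    ),
    class = "emitra_category"
  )
}

#' @export
print.emitra_category <- function(x, ...) {
  cat("<category>", length(x$member_ids), "members:",
      paste(x$member_ids, collapse = " < "), "\n")
  cat("  shared features:", x$shared_feature, "\n")
  cat("  valid:", x$valid, "\n")
  if (!x$valid) print(x$validation[!x$validation$pass, ])
  invisible(x)
}

#' Read-across grouping mode from target and source counts
#'
#' One source chemical serving one target is `one_to_one`; one source
#' serving several targets is `one_to_many`; several sources pooled for one
#' target is `many_to_one`; and several sources for several targets is
#' `many_to_many`.
#'
#' @param n_targets,n_sources Positive integer counts.
#' @return One of `"one_to_one"`, `"one_to_many"`, `"many_to_one"`,
#'   `"many_to_many"`.
#' @export
select_mode <- function(n_targets, n_sources) {
  stopifnot(length(n_targets) == 1L, length(n_sources) == 1L)
  if (n_targets < 1 || n_sources < 1) {
    stop("target and source counts must be at least 1", call. = FALSE)
  }
  if (n_sources == 1) {
    if (n_targets == 1) "one_to_one" else "one_to_many"
  } else {
    if (n_targets == 1) "many_to_one" else "many_to_many"
  }
}
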