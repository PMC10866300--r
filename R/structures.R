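# Structure parsing and elementary descriptors.
#
# SMILES interpretation, canonicalization and formula perception are
# delegated to OpenBabel through ChemmineOB; the atom/bond graph needed by
# the circular fingerprint is extracted from the V2000 MOL block OpenBabel
# writes (a tiny fixed-format reader lives below, because the usual SDF
# container cannot represent single-atom molecules such as methane).

# Conventional IUPAC atomic weights (2021 abridged values), fixed here so
# that molecular weights are bit-reproducible across installations.
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845,
  Cu = 63.546, Zn = 65.38, Br = 79.904, I = 126.904
)

# Default valences used to assign implicit hydrogens to the kekulized
# graph (organic subset; charges are not modelled).
.default_valence <- c(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = 3L,
  S = 2L, Cl = 1L, Br = 1L, I = 1L
)

#' Parse a SMILES string into a structure record
#'
#' Canonicalizes the SMILES through OpenBabel, perceives the molecular
#' formula (implicit hydrogens included) and extracts the heavy-atom graph
#' used by the fingerprint generators. Canonicalization is idempotent:
#' parsing the canonical SMILES of a structure reproduces it.
#'
#' @param smiles A single SMILES string.
#' @param name Optional chemical name carried along for reporting.
#' @return An object of class `emitra_structure` with fields `smiles`
#'   (canonical), `input_smiles`, `name`, `formula` (named integer vector of
#'   element counts, hydrogens included), `heavy_atom_count`,
#'   `carbon_count`, and the internal `atoms`/`bonds` tables.
#' @examples
#' cumene <- parse_structure("CC(C)c1ccccc1", name = "cumene")
#' cumene$formula       # C9 H12
#' cumene$carbon_count  # 9
#' @export
parse_structure <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(trimws(smiles))) {
    stop("invalid SMILES: empty string", call. = FALSE)
  }
  cached <- .cache_get(paste0("parse\r", smiles))
  if (!is.null(cached)) {
    cached$name <- if (is.null(name)) NA_character_ else name
    return(cached)
  }
  can <- .ob_canonical(smiles)
  mol <- .ob_molblock(can)
  graph <- .read_v2000(mol)
  formula <- .formula_from_graph(graph$atoms, graph$bonds)
  out <- structure(
    list(
      smiles = can,
      input_smiles = smiles,
      name = if (is.null(name)) NA_character_ else name,
      formula = formula,
      heavy_atom_count = nrow(graph$atoms),
      carbon_count = if ("C" %in% names(formula)) formula[["C"]] else 0L,
      atoms = graph$atoms,
      bonds = graph$bonds
    ),
    class = "emitra_structure"
  )
  .cache_set(paste0("parse\r", smiles), out)
  out
}

# Session-local memoization of OpenBabel round-trips and fingerprints;
# keys are exact input strings, so cached results are bitwise identical to
# fresh ones.
.emitra_cache <- new.env(parent = emptyenv())
.cache_get <- function(key) {
  if (exists(key, envir = .emitra_cache, inherits = FALSE)) {
    get(key, envir = .emitra_cache, inherits = FALSE)
  }
}
.cache_set <- function(key, value) {
  assign(key, value, envir = .emitra_cache)
  value
}

#' @export
print.emitra_structure <- function(x, ...) {
  cat("<structure>", if (!is.na(x$name)) x$name else "", x$smiles, "\n")
  cat("  formula:", format_formula(x$formula),
      " MW:", round(molecular_weight(x), 3), "amu\n")
  invisible(x)
}

#' Molecular weight from a structure's formula
#'
#' Sum over elements of count times the conventional IUPAC atomic weight.
#' Full precision is returned; round at the reporting boundary (tables in
#' this field print one decimal place).
#'
#' @param s An `emitra_structure` (or a named formula vector).
#' @return Molecular weight in amu.
#' @examples
#' round(molecular_weight(parse_structure("CC(C)c1ccccc1")), 1)  # 120.2
#' @export
molecular_weight <- function(s) {
  formula <- if (inherits(s, "emitra_structure")) s$formula else s
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  unknown <- setdiff(names(formula), names(.atomic_weights))
  if (length(unknown)) {
    stop("no atomic weight tabulated for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(formula * .atomic_weights[names(formula)])
}

#' Format an element-count vector as a Hill-order formula string
#' @param formula Named integer vector of element counts.
#' @return A string such as `"C9H12"`.
#' @export
format_formula <- function(formula) {
  els <- names(formula)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    n <- formula[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

## ---- OpenBabel bridge -----------------------------------------------------

.ob_canonical <- function(smiles) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\tmol"))
  )
  out <- sub("\t.*$", "", sub("\n$", "", out))
  if (!nzchar(out)) {
    stop("invalid SMILES: '", smiles, "' could not be parsed", call. = FALSE)
  }
  out
}

.ob_molblock <- function(smiles) {
  ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tmol"))
}

# Handle on an OpenBabel molecule, for SMARTS matching and bulk properties.
.ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

## ---- V2000 MOL block ------------------------------------------------------

# Minimal reader for the single MOL block OpenBabel emits: counts line,
# fixed-width atom lines (element in columns 32-34) and bond lines.
.read_v2000 <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms)) stop("malformed MOL block counts line", call. = FALSE)
  atoms <- data.frame(element = character(0), stringsAsFactors = FALSE)
  if (natoms > 0) {
    al <- lines[5:(4 + natoms)]
    atoms <- data.frame(
      element = trimws(substr(al, 32, 34)),
      stringsAsFactors = FALSE
    )
  }
  bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(
      a = as.integer(substr(bl, 1, 3)),
      b = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  }
  list(atoms = atoms, bonds = bonds)
}

# Element counts with implicit hydrogens from default valences applied to
# the kekulized graph.
.formula_from_graph <- function(atoms, bonds) {
  n <- nrow(atoms)
  bond_sum <- integer(n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      bond_sum[bonds$a[i]] <- bond_sum[bonds$a[i]] + bonds$order[i]
      bond_sum[bonds$b[i]] <- bond_sum[bonds$b[i]] + bonds$order[i]
    }
  }
  implicit_h <- integer(n)
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    if (el %in% names(.default_valence)) {
      implicit_h[i] <- max(0L, .default_valence[[el]] - bond_sum[i])
    }
  }
  counts <- table(atoms$element)
  formula <- stats::setNames(as.integer(counts), names(counts))
  nh <- sum(implicit_h) +
    (if ("H" %in% names(formula)) formula[["H"]] else 0L)
  formula <- formula[names(formula) != "H"]
  if (nh > 0) formula <- c(formula, H = as.integer(nh))
  # stable order: C, H, then alphabetical
  els <- names(formula)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  formula[ord]
}

# Per-atom implicit hydrogen counts (used by the circular fingerprint).
.implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  bond_sum <- integer(n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      bond_sum[bonds$a[i]] <- bond_sum[bonds$a[i]] + bonds$order[i]
      bond_sum[bonds$b[i]] <- bond_sum[bonds$b[i]] + bonds$order[i]
    }
  }
  vapply(seq_len(n), function(i) {
    el <- atoms$element[i]
    if (el %in% names(.default_valence)) {
      max(0L, .default_valence[[el]] - bond_sum[i])
    } else 0L
  }, integer(1))
}
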