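# Fingerprint generation and Tanimoto similarity.
#
# Two schemes are provided. The default, counted atom pairs, delegates
# feature enumeration to ChemmineR (sdf2ap) and compares feature multisets;
# it is count-sensitive, so a homologue that duplicates a substituent is
# penalized relative to one that merely lacks it — the behaviour expected of
# analogue identification tools in this domain (the closest analogue of
# p-cymene is cumene, not 1,4-diisopropylbenzene). The alternative hashed
# circular scheme (radius-2 environments folded to 2048 bits) is implemented
# here directly and is selectable for scheme-sensitivity analyses. Scores
# are only comparable within one scheme; every fingerprint carries a
# scheme_id and tanimoto() refuses to mix schemes.

#' Fingerprint generation parameters
#'
#' @param scheme `"atompair"` (counted atom pairs, the default) or
#'   `"circular"` (hashed circular substructures).
#' @param radius Environment radius for the circular scheme (bonds).
#' @param n_bits Bit-space size the circular scheme is folded into.
#' @return A `fingerprint_params` list with a `scheme_id` string that is
#'   stamped into every fingerprint generated under these parameters.
#' @export
fingerprint_params <- function(scheme = c("atompair", "circular"),
                               radius = 2L, n_bits = 2048L) {
  scheme <- match.arg(scheme)
  stopifnot(radius >= 0, n_bits >= 2)
  scheme_id <- switch(scheme,
    atompair = "atompair/counted/v1",
    circular = sprintf("circular/r%d/%d/v1", as.integer(radius),
                       as.integer(n_bits))
  )
  structure(list(scheme = scheme, radius = as.integer(radius),
                 n_bits = as.integer(n_bits), scheme_id = scheme_id),
            class = "fingerprint_params")
}

#' Generate a molecular fingerprint
#'
#' Deterministic for fixed parameters. The empty fingerprint (no features)
#' arises only for molecules with fewer than two heavy atoms under the
#' atom-pair scheme; single atoms still receive environment bits under the
#' circular scheme.
#'
#' @param s An `emitra_structure` from [parse_structure()].
#' @param params A [fingerprint_params()] object.
#' @return An `emitra_fingerprint`: feature `ids` (sorted), parallel
#'   `counts`, and the generating `scheme_id`.
#' @export
fingerprint <- function(s, params = fingerprint_params()) {
  stopifnot(inherits(s, "emitra_structure"),
            inherits(params, "fingerprint_params"))
  key <- paste0("fp\r", params$scheme_id, "\r", s$smiles)
  cached <- .cache_get(key)
  if (!is.null(cached)) return(cached)
  feats <- switch(params$scheme,
    atompair = .fp_atompair(s),
    circular = .fp_circular(s, params$radius, params$n_bits)
  )
  .cache_set(key, new_fingerprint(feats$ids, feats$counts, params$scheme_id))
}

new_fingerprint <- function(ids, counts, scheme_id) {
  o <- order(ids)
  structure(list(ids = as.numeric(ids)[o], counts = as.integer(counts)[o],
                 scheme_id = scheme_id),
            class = "emitra_fingerprint")
}

#' Build a fingerprint from an explicit bit set
#'
#' Mainly for algebraic tests and worked examples: wraps a set of integer
#' bit positions as a binary fingerprint.
#'
#' @param bits Integer vector of set positions (duplicates collapse).
#' @param scheme_id Scheme label; fingerprints only compare within a scheme.
#' @export
fingerprint_from_bits <- function(bits, scheme_id = "bits/manual") {
  bits <- unique(as.numeric(bits))
  new_fingerprint(bits, rep(1L, length(bits)), scheme_id)
}

#' @export
print.emitra_fingerprint <- function(x, ...) {
  cat("<fingerprint>", x$scheme_id, "-", length(x$ids), "features,",
      sum(x$counts), "total count\n")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' For feature multisets A and B, `sum(min(A,B)) / sum(max(A,B))`; on binary
#' fingerprints this reduces to the familiar set form, intersection over
#' union. A value of 1 means the fingerprints are identical and 0 that the
#' molecules share no features. Two empty fingerprints compare as 1 (the
#' identity of empty molecules, a documented convention).
#'
#' @param a,b `emitra_fingerprint`s generated under the same scheme.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "emitra_fingerprint"),
            inherits(b, "emitra_fingerprint"))
  if (!identical(a$scheme_id, b$scheme_id)) {
    stop("fingerprint scheme mismatch: '", a$scheme_id, "' vs '",
         b$scheme_id, "' - scores across schemes are meaningless",
         call. = FALSE)
  }
  if (length(a$ids) == 0L && length(b$ids) == 0L) return(1)
  ids <- sort(unique(c(a$ids, b$ids)))
  ca <- cb <- numeric(length(ids))
  ca[match(a$ids, ids)] <- a$counts
  cb[match(b$ids, ids)] <- b$counts
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

## ---- atom-pair scheme (ChemmineR) ----------------------------------------

.fp_atompair <- function(s) {
  if (s$heavy_atom_count < 2L) {
    return(list(ids = numeric(0), counts = integer(0)))
  }
  sdf <- ChemmineR::smiles2sdf(stats::setNames(s$smiles, "mol"))
  apset <- ChemmineR::sdf2ap(sdf)
  codes <- ChemmineR::ap(apset[[1]])
  tab <- table(codes)
  list(ids = as.numeric(names(tab)), counts = as.integer(tab))
}

## ---- hashed circular scheme ----------------------------------------------

# Iteratively refined atom-environment codes (initial invariant: element,
# degree, implicit-H count, bond-order sum), every radius's code folded into
# the bit space. Binary occurrences, not counts.
.fp_circular <- function(s, radius, n_bits) {
  atoms <- s$atoms
  bonds <- s$bonds
  n <- nrow(atoms)
  if (n == 0L) return(list(ids = numeric(0), counts = integer(0)))
  nbr <- rep(list(integer(0)), n)
  ord <- rep(list(integer(0)), n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds$a[i]; b <- bonds$b[i]; o <- bonds$order[i]
      nbr[[a]] <- c(nbr[[a]], b); ord[[a]] <- c(ord[[a]], o)
      nbr[[b]] <- c(nbr[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  nh <- .implicit_h(atoms, bonds)
  z <- match(atoms$element, names(.atomic_weights))
  z[is.na(z)] <- 0L
  deg <- lengths(nbr)
  bsum <- vapply(ord, sum, numeric(1))
  code <- vapply(seq_len(n), function(i) {
    .hash_ints(c(z[i], deg[i], nh[i], bsum[i]))
  }, numeric(1))
  bits <- code %% n_bits
  for (r in seq_len(radius)) {
    code <- vapply(seq_len(n), function(i) {
      if (deg[i] == 0L) return(.hash_ints(c(r, code[i])))
      env <- cbind(ord[[i]], code[nbr[[i]]])
      env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
      .hash_ints(c(r, code[i], as.vector(t(env))))
    }, numeric(1))
    bits <- c(bits, code %% n_bits)
  }
  ids <- sort(unique(bits))
  list(ids = ids, counts = rep(1L, length(ids)))
}

# Deterministic polynomial hash over non-negative integers, arithmetic kept
# inside the exact double range (modulus 2^31 - 1).
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + x + 1) %% 2147483647
  h
}
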