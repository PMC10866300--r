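# Property store: gap analysis and within-category trend filling.
#
# The property vocabulary is fixed (units declared once, no silent
# conversion): mw (amu), bp_c (degrees C), vp_mmhg_25c (mm Hg at 25 C),
# wsol_mg_l (mg/L), logkow (dimensionless). Vapour pressure and water
# solubility span decades across a homologous series, so their trends are
# fitted in log10 domain; the others in linear domain.


#' Property names understood by the package
#' @return Character vector of the five property column names.
#' @export
property_names <- function() .property_names

#' Data-gap analysis over a chemicals table
#'
#' Builds the exhaustive chemical-by-property presence matrix for the
#' requested property set and tallies what is missing.
#'
#' @param chemicals Chemicals table with an `id` column and property
#'   columns; `NA` means missing.
#' @param required Character vector of property columns to audit
#'   (default: all five).
#' @return An `emitra_gap_report`: logical `present` matrix (chemicals by
#'   properties), `missing` data frame (`id`, `property`), and counts.
#' @export
gap_analysis <- function(chemicals, required = property_names()) {
  stopifnot(is.data.frame(chemicals), nrow(chemicals) >= 1L,
            "id" %in% names(chemicals))
  unknown <- setdiff(required, .property_names)
  if (length(unknown)) {
    stop("unknown property name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  present <- matrix(FALSE, nrow(chemicals), length(required),
                    dimnames = list(chemicals$id, required))
  for (p in required) {
    if (p %in% names(chemicals)) present[, p] <- !is.na(chemicals[[p]])
  }
  idx <- which(!present, arr.ind = TRUE)
  missing <- data.frame(
    id = as.character(rownames(present)[idx[, 1]]),
    property = as.character(colnames(present)[idx[, 2]]),
    stringsAsFactors = FALSE
  )
  missing <- missing[order(missing$id, missing$property), , drop = FALSE]
  rownames(missing) <- NULL
  structure(
    list(present = present, missing = missing,
         n_missing = nrow(missing), n_cells = length(present)),
    class = "emitra_gap_report"
  )
}

#' @export
print.emitra_gap_report <- function(x, ...) {
  cat("<gap report>", x$n_missing, "of", x$n_cells, "cells missing\n")
  if (x$n_missing) print(x$missing)
  invisible(x)
}

#' Fill a property gap by within-category trend
#'
#' Fits a least-squares line of the property (log10 of it for vapour
#' pressure and water solubility) against a structural descriptor over the
#' category members that have the value, and evaluates the line at the
#' target's descriptor. When the target lies outside the members'
#' descriptor range the fill is an extrapolation and is flagged as such.
#'
#' @param category An `emitra_category` from [validate_category()], or a
#'   character vector of member ids.
#' @param chemicals Chemicals table holding the members' property values
#'   and `smiles` (used to compute the descriptor).
#' @param property One of [property_names()].
#' @param target_id Id of the member whose value is missing.
#' @param descriptor Structural descriptor for the trend axis; only
#'   `"carbon_count"` (default) and `"mw"` are built in.
#' @return A `trend_fill`: `property`, `value`, `provenance`
#'   (`"trend_filled"`), `extrapolated`, and the `fit` (intercept, slope,
#'   domain, n, descriptor range).
#' @export
fill_by_trend <- function(category, chemicals, property, target_id,
                          descriptor = "carbon_count") {
  member_ids <- if (inherits(category, "emitra_category")) {
    category$member_ids
  } else as.character(category)
  stopifnot(property %in% .property_names, target_id %in% member_ids,
            target_id %in% chemicals$id)
  rows <- chemicals[match(member_ids, chemicals$id), , drop = FALSE]
  if (anyNA(rows$id)) {
    stop("category member(s) absent from chemicals table: ",
         paste(setdiff(member_ids, chemicals$id), collapse = ", "),
         call. = FALSE)
  }
  d <- .descriptor_values(rows, descriptor)
  tgt <- member_ids == target_id
  if (!is.na(rows[[property]][tgt])) {
    stop("target '", target_id, "' already has a value for ", property,
         call. = FALSE)
  }
  have <- !tgt & !is.na(rows[[property]])
  if (sum(have) < 2L) {
    stop("trend requires >= 2 members with a value for ", property,
         call. = FALSE)
  }
  y <- rows[[property]][have]
  log_domain <- property %in% .log_properties
  if (log_domain) {
    if (any(y <= 0)) {
      stop("log-domain trend needs positive values for ", property,
           call. = FALSE)
    }
    y <- log10(y)
  }
  x <- d[have]
  fit <- stats::lm(y ~ x)
  x0 <- d[tgt]
  pred <- unname(stats::predict(fit, data.frame(x = x0)))
  value <- if (log_domain) 10^pred else pred
  structure(
    list(
      property = property,
      target_id = target_id,
      value = value,
      provenance = "trend_filled",
      extrapolated = x0 < min(x) || x0 > max(x),
      fit = list(
        intercept = unname(stats::coef(fit)[1]),
        slope = unname(stats::coef(fit)[2]),
        domain = if (log_domain) "log10" else "linear",
        descriptor = descriptor,
        n = sum(have),
        descriptor_range = range(x)
      )
    ),
    class = "trend_fill"
  )
}

#' @export
print.trend_fill <- function(x, ...) {
  cat("<trend fill>", x$property, "for", x$target_id, "=",
      signif(x$value, 6),
      if (x$extrapolated) "(extrapolated)" else "(interpolated)", "\n")
  invisible(x)
}

.descriptor_values <- function(rows, descriptor) {
  if (descriptor == "carbon_count") {
    vapply(rows$smiles, function(sm) parse_structure(sm)$carbon_count,
           numeric(1), USE.NAMES = FALSE)
  } else if (descriptor == "mw") {
    vapply(rows$smiles, function(sm) molecular_weight(parse_structure(sm)),
           numeric(1), USE.NAMES = FALSE)
  } else {
    stop("unknown descriptor: ", descriptor, call. = FALSE)
  }
}

# Apply a set of trend fills to a chemicals table, never overwriting a
# value whose provenance is measured or database. Returns the table plus
# the fills actually applied.
.apply_fills <- function(chemicals, fills) {
  applied <- list()
  for (f in fills) {
    i <- match(f$target_id, chemicals$id)
    src_col <- paste0(f$property, "_src")
    existing_src <- if (src_col %in% names(chemicals)) {
      chemicals[[src_col]][i]
    } else NA_character_
    if (!is.na(chemicals[[f$property]][i]) &&
        isTRUE(existing_src %in% c("measured", "database"))) {
      next
    }
    if (is.na(chemicals[[f$property]][i])) {
      chemicals[[f$property]][i] <- f$value
      if (!src_col %in% names(chemicals)) chemicals[[src_col]] <- NA_character_
      chemicals[[src_col]][i] <- "trend_filled"
      applied <- c(applied, list(f))
    }
  }
  list(chemicals = chemicals, applied = applied)
}
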