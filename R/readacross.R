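# Read-across factors and the four quantitative estimation modes.

#' Per-property read-across factors
#'
#' One factor per requested property: the value in the target situation
#' divided by the value in the source situation. A factor of 1 means the
#' property gives no reason to scale the source emission.
#'
#' @param target,source Single rows of a chemicals table holding the
#'   property columns.
#' @param properties Character vector of [property_names()] to use.
#' @return Data frame `property`, `target_value`, `source_value`, `factor`.
#' @export
compute_factors <- function(target, source, properties) {
  stopifnot(is.data.frame(target), nrow(target) == 1L,
            is.data.frame(source), nrow(source) == 1L,
            length(properties) >= 1L)
  out <- lapply(properties, function(p) {
    if (!p %in% names(target) || is.na(target[[p]])) {
      stop("target lacks property '", p, "'", call. = FALSE)
    }
    if (!p %in% names(source) || is.na(source[[p]])) {
      stop("source lacks property '", p, "'", call. = FALSE)
    }
    sv <- source[[p]]
    if (sv == 0) stop("source value for '", p, "' is zero", call. = FALSE)
    data.frame(property = p, target_value = target[[p]], source_value = sv,
               factor = target[[p]] / sv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Combine per-property factors into one overall factor
#'
#' The default combines by geometric mean, treating each property ratio as
#' an independent multiplicative signal. `"product"` multiplies them all
#' (each ratio applied in full), and `"unity"` ignores them — the choice
#' when target and source properties are judged so similar that the source
#' emissions carry over unchanged.
#'
#' @param factors Data frame from [compute_factors()] (or numeric vector).
#' @param rule `"geomean"`, `"product"` or `"unity"`.
#' @return A single numeric factor.
#' @export
overall_factor <- function(factors, rule = c("geomean", "product", "unity")) {
  rule <- match.arg(rule)
  f <- if (is.data.frame(factors)) factors$factor else as.numeric(factors)
  if (rule == "unity") return(1)
  if (length(f) < 1L) stop("no factors supplied", call. = FALSE)
  switch(rule,
    geomean = {
      if (any(f <= 0)) {
        stop("geometric mean requires positive factors", call. = FALSE)
      }
      exp(mean(log(f)))
    },
    product = prod(f)
  )
}

## ---- estimate objects -----------------------------------------------------

# Single evaluation path for every mode; audit_estimate() re-runs exactly
# this function, so a stored estimate must reproduce bit-for-bit.
.estimate_value <- function(mode, chain, factor, target_descriptor = NA) {
  switch(mode,
    closest = chain$value[1] * factor,
    average = mean(chain$value) * factor,
    conservative = max(chain$value) * factor,
    trend = {
      fit <- stats::lm(y ~ x,
                       data = data.frame(y = log10(chain$value),
                                         x = chain$descriptor))
      10^unname(stats::predict(fit, data.frame(x = target_descriptor))) *
        factor
    },
    stop("unknown estimation mode '", mode, "'", call. = FALSE)
  )
}

new_estimate <- function(process_id, species_id, medium, mode, chain,
                         factor, factor_breakdown = NULL,
                         target_descriptor = NA_real_, role = NA_character_,
                         extrapolated = FALSE) {
  structure(
    list(
      process_id = process_id, species_id = species_id, medium = medium,
      value = .estimate_value(mode, chain, factor, target_descriptor),
      basis = "read_across", mode = mode, overall_factor = factor,
      factor_breakdown = factor_breakdown, source_chain = chain,
      target_descriptor = target_descriptor, role = role,
      extrapolated = extrapolated, uncertainty = NULL
    ),
    class = "emitra_estimate"
  )
}

#' @export
print.emitra_estimate <- function(x, ...) {
  cat(sprintf("<estimate> %s @ %s (%s): %.3e kg/kg [mode %s, factor %.4g]\n",
              x$species_id, x$process_id, x$medium, x$value, x$mode,
              x$overall_factor))
  if (!is.null(x$uncertainty)) cat("  uncertainty:", x$uncertainty$grade, "\n")
  invisible(x)
}

#' Flatten a list of estimates into an emissions-style table
#' @param estimates List of `emitra_estimate` objects.
#' @return Data frame `process_id`, `species_id`, `medium`,
#'   `kg_per_kg_product`, `basis`, `mode`, `overall_factor`, `uncertainty`.
#' @export
estimates_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(
      process_id = e$process_id, species_id = e$species_id,
      medium = e$medium, kg_per_kg_product = e$value, basis = e$basis,
      mode = e$mode, overall_factor = e$overall_factor,
      uncertainty = if (is.null(e$uncertainty)) NA_character_
                    else e$uncertainty$grade,
      stringsAsFactors = FALSE
    )
  }))
}

#' Re-derive an estimate from its own provenance
#'
#' Recomputes the estimate value from the stored source chain, mode and
#' overall factor, through the same evaluation path that produced it. The
#' result must match the stored value exactly; a mismatch means the
#' provenance no longer explains the number.
#'
#' @param estimate An `emitra_estimate`.
#' @return List `value` (recomputed), `stored`, `consistent` (identical).
#' @export
audit_estimate <- function(estimate) {
  stopifnot(inherits(estimate, "emitra_estimate"))
  v <- .estimate_value(estimate$mode, estimate$source_chain,
                       estimate$overall_factor, estimate$target_descriptor)
  list(value = v, stored = estimate$value,
       consistent = identical(v, estimate$value))
}

## ---- mode 1: closest source chemical --------------------------------------

#' Read across emissions from the closest source process
#'
#' Every measured emission row of the source process whose species has a
#' counterpart in the role mapping is scaled by the overall factor and
#' relabelled to the corresponding target species. Source rows whose
#' species is unmatched are dropped, with a warning entry.
#'
#' @param target_proc `emitra_process` whose emissions are being estimated.
#' @param source_proc `emitra_process` with measured emissions.
#' @param role_map Result of [map_species_roles()].
#' @param emissions Emissions table (`process_id`, `species_id`, `medium`,
#'   `kg_per_kg_product`, `basis`).
#' @param factor Overall read-across factor (default 1).
#' @param molar_basis Carry values on a molar rather than a mass basis:
#'   each row is additionally scaled by the target/source species
#'   molecular-weight ratio. Off by default — the mass basis (kg/kg
#'   product) carries the source value unchanged, which is the worked
#'   example's behaviour.
#' @param chemicals Chemicals table with SMILES; required when
#'   `molar_basis` is `TRUE`.
#' @return List `estimates` (list of `emitra_estimate`) and `warnings`.
#' @export
estimate_closest <- function(target_proc, source_proc, role_map, emissions,
                             factor = 1, molar_basis = FALSE,
                             chemicals = NULL) {
  rows <- emissions[emissions$process_id == source_proc$process_id, ,
                    drop = FALSE]
  rows <- rows[rows$basis == "measured", , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("source process '", source_proc$process_id,
         "' has no measured emissions; use a category mode instead",
         call. = FALSE)
  }
  if (isTRUE(molar_basis) && is.null(chemicals)) {
    stop("molar_basis = TRUE needs the chemicals table for weights",
         call. = FALSE)
  }
  species_mw <- function(id) {
    molecular_weight(parse_structure(
      chemicals$smiles[match(id, chemicals$id)], name = id))
  }
  warnings <- character(0)
  estimates <- list()
  for (i in seq_len(nrow(rows))) {
    j <- match(rows$species_id[i], role_map$map$source_id)
    if (is.na(j)) {
      warnings <- c(warnings, sprintf(
        "source emission row for '%s' dropped: no counterpart in target process",
        rows$species_id[i]))
      next
    }
    row_factor <- factor
    if (isTRUE(molar_basis)) {
      row_factor <- factor * species_mw(role_map$map$target_id[j]) /
        species_mw(rows$species_id[i])
    }
    estimates <- c(estimates, list(new_estimate(
      process_id = target_proc$process_id,
      species_id = role_map$map$target_id[j],
      medium = rows$medium[i],
      mode = "closest",
      chain = data.frame(process_id = rows$process_id[i],
                         species_id = rows$species_id[i],
                         value = rows$kg_per_kg_product[i],
                         descriptor = NA_real_,
                         stringsAsFactors = FALSE),
      factor = row_factor,
      role = role_map$map$role[j]
    )))
  }
  list(estimates = estimates, warnings = warnings)
}

## ---- mode 2: category trend ----------------------------------------------

#' Estimate emissions from a within-category trend
#'
#' For every participant of the target process, collects the matching
#' (same-role, most similar species) measured emission value from each
#' source process, regresses log10(emission) on the structural descriptor
#' of the source products, and evaluates the line at the target product's
#' descriptor. Requires at least two source processes with usable values
#' per role; extrapolation beyond the descriptor range is flagged.
#'
#' @param sources List of `emitra_process` records with measured emissions.
#' @param emissions Emissions table covering the sources.
#' @param target_proc Target `emitra_process`.
#' @param chemicals Chemicals table (SMILES for descriptor/similarity).
#' @param descriptor `"carbon_count"` (default) or `"mw"`, computed on each
#'   process's product chemical.
#' @param params Fingerprint scheme for the within-role species matching.
#' @param factor Overall read-across factor applied on top of the trend
#'   (default 1).
#' @return List `estimates`, `warnings`.
#' @export
estimate_trend <- function(sources, emissions, target_proc, chemicals,
                           descriptor = "carbon_count",
                           params = fingerprint_params(), factor = 1) {
  stopifnot(length(sources) >= 2L)
  target_d <- .descriptor_values(
    chemicals[match(target_proc$product_id, chemicals$id), , drop = FALSE],
    descriptor)
  warnings <- character(0)
  estimates <- list()
  for (k in seq_len(nrow(target_proc$participants))) {
    t_sp <- target_proc$participants$chemical_id[k]
    t_role <- target_proc$participants$role[k]
    chain <- list()
    for (src in sources) {
      rm <- map_species_roles(target_proc, src, chemicals, params)
      j <- which(rm$map$target_id == t_sp & rm$map$role == t_role)
      if (!length(j)) next
      src_sp <- rm$map$source_id[j[1]]
      rows <- emissions[emissions$process_id == src$process_id &
                          emissions$species_id == src_sp &
                          emissions$basis == "measured", , drop = FALSE]
      if (!nrow(rows)) next
      d <- .descriptor_values(
        chemicals[match(src$product_id, chemicals$id), , drop = FALSE],
        descriptor)
      chain <- c(chain, list(data.frame(
        process_id = src$process_id, species_id = src_sp,
        value = rows$kg_per_kg_product[1], descriptor = d,
        stringsAsFactors = FALSE)))
    }
    if (length(chain) < 2L) {
      warnings <- c(warnings, sprintf(
        "species '%s' (%s): trend requires >= 2 source values, found %d",
        t_sp, t_role, length(chain)))
      next
    }
    chain <- do.call(rbind, chain)
    if (any(chain$value <= 0)) {
      warnings <- c(warnings, sprintf(
        "species '%s' (%s): non-positive source emission, trend skipped",
        t_sp, t_role))
      next
    }
    estimates <- c(estimates, list(new_estimate(
      process_id = target_proc$process_id, species_id = t_sp,
      medium = emissions$medium[match(chain$process_id[1],
                                      emissions$process_id)],
      mode = "trend", chain = chain, factor = factor,
      target_descriptor = target_d, role = t_role,
      extrapolated = target_d < min(chain$descriptor) ||
        target_d > max(chain$descriptor)
    )))
  }
  list(estimates = estimates, warnings = warnings)
}

## ---- modes 3 and 4: average and conservative -------------------------------

#' Average of source endpoint values
#' @param values Numeric vector of at least two source emission values.
#' @return Arithmetic mean.
#' @export
estimate_average <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) {
    stop("averaging requires >= 2 source values", call. = FALSE)
  }
  mean(values)
}

#' Most conservative source endpoint value
#'
#' Conservative here means protective of exposure: the highest emission
#' among the sources.
#'
#' @param values Numeric vector of at least two source emission values.
#' @return Maximum value.
#' @export
estimate_conservative <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) {
    stop("conservative selection requires >= 2 source values", call. = FALSE)
  }
  max(values)
}

# Pooled estimation (average/conservative) across >= 2 mapped sources,
# per target participant. Shares the chain-collection logic with the trend
# mode but aggregates instead of regressing.
.estimate_pooled <- function(mode, sources, emissions, target_proc,
                             chemicals, params = fingerprint_params(),
                             factor = 1) {
  stopifnot(mode %in% c("average", "conservative"), length(sources) >= 2L)
  warnings <- character(0)
  estimates <- list()
  for (k in seq_len(nrow(target_proc$participants))) {
    t_sp <- target_proc$participants$chemical_id[k]
    t_role <- target_proc$participants$role[k]
    chain <- list()
    medium <- NA_character_
    for (src in sources) {
      rm <- map_species_roles(target_proc, src, chemicals, params)
      j <- which(rm$map$target_id == t_sp & rm$map$role == t_role)
      if (!length(j)) next
      src_sp <- rm$map$source_id[j[1]]
      rows <- emissions[emissions$process_id == src$process_id &
                          emissions$species_id == src_sp &
                          emissions$basis == "measured", , drop = FALSE]
      if (!nrow(rows)) next
      medium <- rows$medium[1]
      chain <- c(chain, list(data.frame(
        process_id = src$process_id, species_id = src_sp,
        value = rows$kg_per_kg_product[1], descriptor = NA_real_,
        stringsAsFactors = FALSE)))
    }
    if (length(chain) < 2L) {
      warnings <- c(warnings, sprintf(
        "species '%s' (%s): %s requires >= 2 source values, found %d",
        t_sp, t_role, mode, length(chain)))
      next
    }
    estimates <- c(estimates, list(new_estimate(
      process_id = target_proc$process_id, species_id = t_sp,
      medium = medium, mode = mode, chain = do.call(rbind, chain),
      factor = factor, role = t_role
    )))
  }
  list(estimates = estimates, warnings = warnings)
}
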