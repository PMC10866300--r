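# Manufacturing process records, compatibility checks and species role
# mapping.


#' Assemble a process record
#'
#' @param process_id,product_id Identifiers; the product must appear among
#'   the participants with role `"product"`, and only once.
#' @param participants Data frame with columns `chemical_id`, `role`
#'   (reactant, solvent, catalyst, auxiliary, product); ids unique.
#' @param catalyst_class One of solid_acid, liquid_acid, base, metal,
#'   enzyme, none, other.
#' @param temperature_c,time_h Operating conditions; `NA` when unknown.
#' @param controls Character vector of pollution-control technologies.
#' @param production_volume Annual production, `NA` when unknown.
#' @return An `emitra_process` list.
#' @export
process_record <- function(process_id, product_id, participants,
                           catalyst_class = "other",
                           temperature_c = NA_real_, time_h = NA_real_,
                           controls = character(0),
                           production_volume = NA_real_) {
  stopifnot(is.data.frame(participants),
            all(c("chemical_id", "role") %in% names(participants)))
  if (!catalyst_class %in% .catalyst_classes) {
    stop("unknown catalyst class '", catalyst_class, "'", call. = FALSE)
  }
  bad_role <- setdiff(participants$role, .roles)
  if (length(bad_role)) {
    stop("unknown participant role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(participants$chemical_id)) {
    stop("participant ids must be unique within a process", call. = FALSE)
  }
  prod <- participants$chemical_id[participants$role == "product"]
  if (length(prod) != 1L) {
    stop("process '", process_id, "' must have exactly one product role",
         call. = FALSE)
  }
  if (prod != product_id) {
    stop("product participant '", prod, "' does not match product_id '",
         product_id, "'", call. = FALSE)
  }
  structure(
    list(process_id = process_id, product_id = product_id,
         participants = participants[, c("chemical_id", "role")],
         catalyst_class = catalyst_class,
         temperature_c = as.numeric(temperature_c),
         time_h = as.numeric(time_h),
         controls = as.character(controls),
         production_volume = as.numeric(production_volume)),
    class = "emitra_process"
  )
}

#' @export
print.emitra_process <- function(x, ...) {
  cat("<process>", x$process_id, "->", x$product_id,
      sprintf("[%s]", x$catalyst_class), "\n")
  for (i in seq_len(nrow(x$participants))) {
    cat("  ", x$participants$chemical_id[i],
        sprintf("(%s)", x$participants$role[i]), "\n")
  }
  invisible(x)
}

#' Check whether two processes are similar enough for read-across
#'
#' A differing catalyst class makes the pair incompatible (a solid-acid
#' process cannot be read across from a liquid-acid one). With matching
#' catalysts the pair is compatible, but large differences in operating
#' conditions or differing pollution-control sets raise warnings that feed
#' the uncertainty grade. Conditions that are unknown on either side are
#' noted but not compared.
#'
#' @param target,source `emitra_process` records.
#' @param max_temp_diff_c Temperature difference above which a warning is
#'   raised (default 50).
#' @param max_time_ratio Ratio of the longer to the shorter reaction time
#'   above which a warning is raised (default 2).
#' @return List with `compatible` (logical), `warnings` (character) and
#'   `reasons` (character; every check is always listed).
#' @export
check_process_compatibility <- function(target, source,
                                        max_temp_diff_c = 50,
                                        max_time_ratio = 2) {
  stopifnot(inherits(target, "emitra_process"),
            inherits(source, "emitra_process"))
  reasons <- character(0)
  warn <- character(0)
  compatible <- TRUE

  if (!identical(target$catalyst_class, source$catalyst_class)) {
    compatible <- FALSE
    reasons <- c(reasons, sprintf(
      "catalyst class differs: target %s vs source %s",
      target$catalyst_class, source$catalyst_class))
  } else {
    reasons <- c(reasons,
                 sprintf("catalyst class matches (%s)", target$catalyst_class))
  }

  if (is.na(target$temperature_c) || is.na(source$temperature_c)) {
    reasons <- c(reasons, "temperature not compared (unknown)")
  } else {
    dt <- abs(target$temperature_c - source$temperature_c)
    reasons <- c(reasons, sprintf("temperature difference %.1f C", dt))
    if (dt > max_temp_diff_c) {
      warn <- c(warn, sprintf("temperature differs by %.1f C (> %.0f)",
                              dt, max_temp_diff_c))
    }
  }

  if (is.na(target$time_h) || is.na(source$time_h)) {
    reasons <- c(reasons, "reaction time not compared (unknown)")
  } else {
    ratio <- max(target$time_h, source$time_h) /
      max(min(target$time_h, source$time_h), .Machine$double.eps)
    reasons <- c(reasons, sprintf("reaction time ratio %.2f", ratio))
    if (ratio > max_time_ratio) {
      warn <- c(warn, sprintf("reaction time ratio %.2f (> %.1f)",
                              ratio, max_time_ratio))
    }
  }

  diff_controls <- union(setdiff(target$controls, source$controls),
                         setdiff(source$controls, target$controls))
  if (length(diff_controls)) {
    warn <- c(warn, paste("pollution controls differ:",
                          paste(diff_controls, collapse = ", ")))
    reasons <- c(reasons, "pollution control sets differ")
  } else {
    reasons <- c(reasons, "pollution controls match")
  }

  list(compatible = compatible, warnings = warn, reasons = reasons)
}

#' Map source process species onto target process species by role
#'
#' The product maps to the product. Within every other role the source
#' participants are matched greedily to the target participants by highest
#' Tanimoto similarity (ties broken by smaller molecular-weight difference,
#' then lexicographic id, so the mapping is deterministic). Source species
#' with no counterpart in the target role are reported unmatched; their
#' emission rows are dropped by the estimators, with a warning.
#'
#' @param target,source `emitra_process` records.
#' @param chemicals Chemicals table supplying SMILES for every participant.
#' @param params Fingerprint scheme used for the similarity matching.
#' @return List with `map` (data frame `source_id`, `target_id`, `role`,
#'   `similarity`) and `unmatched` (source ids with no counterpart).
#' @export
map_species_roles <- function(target, source, chemicals,
                              params = fingerprint_params()) {
  stopifnot(inherits(target, "emitra_process"),
            inherits(source, "emitra_process"))
  all_ids <- union(target$participants$chemical_id,
                   source$participants$chemical_id)
  missing <- setdiff(all_ids, chemicals$id)
  if (length(missing)) {
    stop("participants absent from chemicals table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structs <- lapply(all_ids, function(id) {
    parse_structure(chemicals$smiles[match(id, chemicals$id)], name = id)
  })
  names(structs) <- all_ids
  fps <- lapply(structs, fingerprint, params = params)
  mws <- vapply(structs, molecular_weight, numeric(1))

  map <- data.frame(source_id = character(0), target_id = character(0),
                    role = character(0), similarity = numeric(0),
                    stringsAsFactors = FALSE)
  map <- rbind(map, data.frame(
    source_id = source$product_id, target_id = target$product_id,
    role = "product",
    similarity = tanimoto(fps[[source$product_id]],
                          fps[[target$product_id]]),
    stringsAsFactors = FALSE
  ))
  unmatched <- character(0)

  for (role in setdiff(.roles, "product")) {
    src <- sort(source$participants$chemical_id[
      source$participants$role == role])
    tgt <- sort(target$participants$chemical_id[
      target$participants$role == role])
    while (length(src) && length(tgt)) {
      # score all remaining pairs, take the globally best one
      grid <- expand.grid(s = src, t = tgt, stringsAsFactors = FALSE)
      grid$sim <- mapply(function(s, t) tanimoto(fps[[s]], fps[[t]]),
                         grid$s, grid$t)
      grid$dmw <- mapply(function(s, t) abs(mws[[s]] - mws[[t]]),
                         grid$s, grid$t)
      grid <- grid[order(-grid$sim, grid$dmw, grid$s, grid$t), , drop = FALSE]
      best <- grid[1, ]
      map <- rbind(map, data.frame(
        source_id = best$s, target_id = best$t, role = role,
        similarity = best$sim, stringsAsFactors = FALSE))
      src <- setdiff(src, best$s)
      tgt <- setdiff(tgt, best$t)
    }
    unmatched <- c(unmatched, src)
  }
  rownames(map) <- NULL
  list(map = map, unmatched = unmatched)
}
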