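# The read-across framework: identify, characterize, select analogues,
# analyse and fill data gaps, compare processes, estimate, iterate, and
# grade uncertainty. Failures halt the run with the failing step marked in
# the report rather than raising.

.default_config <- function(config) {
  defaults <- list(
    mode = "auto", factor_rule = "geomean",
    factor_properties = "vp_mmhg_25c", cutoff = 0.25,
    fingerprint_scheme = "atompair",
    similarity_thresholds = c(low = 0.5, moderate = 0.25),
    max_temp_diff_c = 50, max_time_ratio = 2,
    descriptor = "carbon_count", fill_gaps = TRUE, iterate = TRUE,
    molar_basis = FALSE
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  config$similarity_thresholds <- unlist(config$similarity_thresholds)
  stopifnot(
    is.data.frame(config$chemicals), is.list(config$processes),
    is.data.frame(config$emissions), !is.null(config$target_id),
    config$mode %in% c("auto", "closest", "trend", "average",
                       "conservative"),
    config$factor_rule %in% c("geomean", "product", "unity")
  )
  config
}

#' Run the full read-across emission estimation framework
#'
#' Executes the framework steps in order: (1) identify the target chemical
#' and its process, (2) characterize its structure, (3) rank analogue
#' source chemicals and validate the category, (4) analyse property data
#' gaps and compute trend fills, (5) check process compatibility of each
#' candidate source, (6) estimate the target process emissions under the
#' requested mode with read-across factors, (7) re-run the estimation with
#' gap-filled values when fills were computed, then grade every estimate's
#' uncertainty. An unrecoverable failure marks the step and halts; the
#' partial report is still returned.
#'
#' @param config Configuration list (or the result of
#'   [read_run_config()]): `chemicals` table, `processes` (named list of
#'   `emitra_process`), `emissions` table, `target_id`, optional
#'   `target_process_id`, `mode` (`"auto"`, `"closest"`, `"trend"`,
#'   `"average"`, `"conservative"`), `factor_rule` (`"geomean"`,
#'   `"product"`, `"unity"`), `factor_properties`, `cutoff`,
#'   `fingerprint_scheme`, `similarity_thresholds`, `max_temp_diff_c`,
#'   `max_time_ratio`, `descriptor`, `fill_gaps`, `iterate`.
#' @return An `emitra_report`.
#' @examples
#' cs <- load_case_study()
#' rep <- run_framework(c(cs, list(mode = "closest", factor_rule = "unity")))
#' estimates_table(rep$estimates)
#' @export
run_framework <- function(config) {
  cfg <- .default_config(config)
  params <- fingerprint_params(cfg$fingerprint_scheme)
  steps <- list()
  note <- function(step, name, status, detail) {
    steps[[length(steps) + 1L]] <<- list(step = step, name = name,
                                         status = status, detail = detail)
  }
  report <- structure(
    list(target_id = cfg$target_id, target_process_id = NULL,
         mode = cfg$mode, grouping = NULL, factor_rule = cfg$factor_rule,
         analogues = NULL, category = NULL, gap_report = NULL,
         fills = list(), compatibility = list(), role_map = NULL,
         factors = NULL, overall_factor = NA_real_, estimates = list(),
         warnings = character(0), steps = NULL, iterations = 1L,
         halted = FALSE, halt_reason = NULL),
    class = "emitra_report"
  )
  halt <- function(step, name, reason) {
    note(step, name, "halt", reason)
    report$halted <- TRUE
    report$halt_reason <- reason
    report$steps <- steps
    report
  }

  ## 1 -- problem identification
  chem <- cfg$chemicals
  if (!cfg$target_id %in% chem$id) {
    return(halt(1, "identify", paste0("target '", cfg$target_id,
                                      "' not in chemicals table")))
  }
  tp_id <- cfg$target_process_id
  if (is.null(tp_id)) {
    hit <- vapply(cfg$processes, function(p) p$product_id == cfg$target_id,
                  logical(1))
    if (!any(hit)) {
      return(halt(1, "identify", "no process produces the target chemical"))
    }
    tp_id <- names(cfg$processes)[which(hit)[1]]
  }
  if (!tp_id %in% names(cfg$processes)) {
    return(halt(1, "identify", paste0("unknown target process '", tp_id,
                                      "'")))
  }
  tproc <- cfg$processes[[tp_id]]
  report$target_process_id <- tp_id
  note(1, "identify", "ok", sprintf("target %s via process %s",
                                    cfg$target_id, tp_id))

  ## 2 -- characterization
  trow <- chem[chem$id == cfg$target_id, , drop = FALSE]
  tstruct <- tryCatch(parse_structure(trow$smiles, name = trow$id),
                      error = function(e) e)
  if (inherits(tstruct, "error")) {
    return(halt(2, "characterize", conditionMessage(tstruct)))
  }
  note(2, "characterize", "ok",
       sprintf("target %s (%s), %d carbons", cfg$target_id,
               format_formula(tstruct$formula), tstruct$carbon_count))

  ## 3 -- analogue selection and category validation
  source_procs <- cfg$processes[names(cfg$processes) != tp_id]
  candidates <- unique(vapply(source_procs, function(p) p$product_id,
                              character(1)))
  candidates <- setdiff(candidates, cfg$target_id)
  if (!length(candidates)) {
    return(halt(3, "analogue_selection", "no candidate source processes"))
  }
  measured_ids <- unique(unlist(lapply(source_procs, function(p) {
    rows <- cfg$emissions[cfg$emissions$process_id == p$process_id &
                            cfg$emissions$basis == "measured", ]
    if (nrow(rows)) p$product_id else character(0)
  })))
  matches <- find_analogues(trow,
                            chem[chem$id %in% candidates, , drop = FALSE],
                            cutoff = cfg$cutoff, params = params,
                            measured_ids = measured_ids)
  report$analogues <- matches
  if (!nrow(matches)) {
    return(halt(3, "analogue_selection",
                sprintf("no analogue at or above cutoff %.2f", cfg$cutoff)))
  }
  usable <- matches[matches$has_measured_emissions, , drop = FALSE]
  if (!nrow(usable)) {
    return(halt(3, "analogue_selection",
                "no analogue has measured emissions"))
  }
  members <- chem[chem$id %in% c(cfg$target_id, usable$source_id), ,
                  drop = FALSE]
  category <- if (nrow(members) >= 2L) validate_category(members) else NULL
  report$category <- category
  mode <- cfg$mode
  if (mode == "auto") {
    mode <- if (!is.null(category) && category$valid && nrow(usable) >= 2L) {
      "trend"
    } else "closest"
  }
  report$mode <- mode
  report$grouping <- select_mode(1L, max(1L, nrow(usable)))
  note(3, "analogue_selection", "ok",
       sprintf("%d analogue(s); rank 1 = %s (similarity %.4f); mode %s",
               nrow(matches), matches$source_id[1], matches$similarity[1],
               mode))

  ## 4 -- data gap analysis and trend-fill computation
  gap_scope <- members
  report$gap_report <- gap_analysis(gap_scope)
  fills <- list()
  if (isTRUE(cfg$fill_gaps) && report$gap_report$n_missing > 0 &&
      !is.null(category)) {
    for (i in seq_len(nrow(report$gap_report$missing))) {
      m <- report$gap_report$missing[i, ]
      f <- tryCatch(
        fill_by_trend(category, chem, m$property, m$id,
                      descriptor = cfg$descriptor),
        error = function(e) NULL
      )
      if (!is.null(f)) fills <- c(fills, list(f))
    }
  }
  report$fills <- fills
  note(4, "gap_analysis", "ok",
       sprintf("%d gap(s), %d fillable by trend",
               report$gap_report$n_missing, length(fills)))

  ## 5 -- process comparison
  compat <- list()
  compatible_ids <- character(0)
  for (sid in usable$source_id) {
    sprocs <- Filter(function(p) p$product_id == sid, source_procs)
    cr <- check_process_compatibility(tproc, sprocs[[1]],
                                      max_temp_diff_c = cfg$max_temp_diff_c,
                                      max_time_ratio = cfg$max_time_ratio)
    cr$source_id <- sid
    cr$process_id <- sprocs[[1]]$process_id
    compat[[sid]] <- cr
    if (cr$compatible) compatible_ids <- c(compatible_ids, sid)
  }
  report$compatibility <- compat
  if (!length(compatible_ids)) {
    reasons <- unlist(lapply(compat, function(cr) {
      paste0(cr$source_id, ": ", cr$reasons[1])
    }))
    return(halt(5, "process_comparison",
                paste("no compatible source process -",
                      paste(reasons, collapse = "; "))))
  }
  note(5, "process_comparison", "ok",
       sprintf("%d of %d source process(es) compatible",
               length(compatible_ids), length(compat)))

  ## 6 -- estimation (with step-7 iteration on gap-filled values)
  run_estimation <- function(chem_tab, pass) {
    trow_p <- chem_tab[chem_tab$id == cfg$target_id, , drop = FALSE]
    if (mode == "closest") {
      chosen <- compatible_ids[1]
      sproc <- Filter(function(p) p$product_id == chosen, source_procs)[[1]]
      factors <- NULL
      trend_filled_used <- FALSE
      if (cfg$factor_rule == "unity") {
        ov <- 1
      } else {
        srow <- chem_tab[chem_tab$id == chosen, , drop = FALSE]
        factors <- tryCatch(
          compute_factors(trow_p, srow, cfg$factor_properties),
          error = function(e) e)
        if (inherits(factors, "error")) {
          return(list(error = conditionMessage(factors)))
        }
        ov <- overall_factor(factors, cfg$factor_rule)
        src_cols <- paste0(cfg$factor_properties, "_src")
        trend_filled_used <- any(vapply(src_cols, function(sc) {
          isTRUE(trow_p[[sc]] == "trend_filled") ||
            isTRUE(srow[[sc]] == "trend_filled")
        }, logical(1)))
      }
      rm <- map_species_roles(tproc, sproc, chem_tab, params)
      est <- estimate_closest(tproc, sproc, rm, cfg$emissions, factor = ov,
                              molar_basis = cfg$molar_basis,
                              chemicals = chem_tab)
      list(estimates = est$estimates, warnings = est$warnings,
           factors = factors, overall = ov, role_map = rm,
           chosen = chosen, trend_filled_used = trend_filled_used)
    } else {
      srcs <- lapply(compatible_ids, function(sid) {
        Filter(function(p) p$product_id == sid, source_procs)[[1]]
      })
      if (length(srcs) < 2L) {
        return(list(error = sprintf(
          "mode '%s' needs >= 2 compatible sources with measured emissions",
          mode)))
      }
      est <- if (mode == "trend") {
        estimate_trend(srcs, cfg$emissions, tproc, chem_tab,
                       descriptor = cfg$descriptor, params = params)
      } else {
        .estimate_pooled(mode, srcs, cfg$emissions, tproc, chem_tab,
                         params = params)
      }
      list(estimates = est$estimates, warnings = est$warnings,
           factors = NULL, overall = 1, role_map = NULL,
           chosen = compatible_ids, trend_filled_used = FALSE)
    }
  }

  pass1 <- run_estimation(chem, 1L)
  result <- pass1
  iterated <- FALSE
  if (length(fills) &&
      (isTRUE(cfg$iterate) || !is.null(pass1$error))) {
    applied <- .apply_fills(chem, fills)
    if (length(applied$applied)) {
      result <- run_estimation(applied$chemicals, 2L)
      iterated <- TRUE
      report$iterations <- 2L
    }
  }
  if (!is.null(result$error)) {
    return(halt(6, "estimation", result$error))
  }
  if (is.null(pass1$error)) {
    note(6, "estimation", "ok",
         sprintf("%d estimate(s), mode %s, overall factor %.6g",
                 length(result$estimates), mode, result$overall))
  } else {
    note(6, "estimation", "ok",
         "first pass failed on missing properties; gap-filled pass used")
  }
  note(7, "iteration", "ok",
       if (iterated) "re-ran estimation with trend-filled properties"
       else "no iteration needed")
  report$factors <- result$factors
  report$overall_factor <- result$overall
  report$role_map <- result$role_map
  report$warnings <- c(report$warnings, result$warnings)

  ## final -- uncertainty assessment
  estimates <- lapply(result$estimates, function(e) {
    if (e$mode == "closest") {
      chosen <- result$chosen
      sim <- matches$similarity[match(chosen, matches$source_id)]
      pc <- compat[[chosen]]
    } else {
      used <- unlist(result$chosen)
      sim <- min(matches$similarity[match(used, matches$source_id)])
      worst <- which.max(vapply(used, function(sid) {
        cr <- compat[[sid]]
        if (!cr$compatible) 3L else if (length(cr$warnings)) 2L else 1L
      }, integer(1)))
      pc <- compat[[used[worst]]]
    }
    e$uncertainty <- grade_uncertainty(
      similarity = sim, process_compat = pc, source_basis = "measured",
      trend_filled_properties = isTRUE(result$trend_filled_used),
      extrapolated = isTRUE(e$extrapolated),
      thresholds = cfg$similarity_thresholds
    )
    e
  })
  report$estimates <- estimates
  note(8, "uncertainty", "ok",
       paste(unique(vapply(estimates, function(e) e$uncertainty$grade,
                           character(1))), collapse = ", "))
  report$steps <- steps
  report
}

#' @export
print.emitra_report <- function(x, ...) {
  cat("<read-across report> target:", x$target_id, "process:",
      x$target_process_id %||% "?", "\n")
  cat("  mode:", x$mode, " grouping:", x$grouping %||% "?",
      " factor rule:", x$factor_rule,
      sprintf(" overall factor: %.6g", x$overall_factor), "\n")
  if (x$halted) {
    cat("  HALTED:", x$halt_reason, "\n")
  } else if (length(x$estimates)) {
    cat("  estimates:\n")
    tab <- estimates_table(x$estimates)
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-12s %-5s %.3e kg/kg  [%s]\n", tab$species_id[i],
                  tab$medium[i], tab$kg_per_kg_product[i],
                  tab$uncertainty[i]))
    }
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
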