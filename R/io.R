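# Readers and writers for the package's plain-text interfaces.
#
# All tables are UTF-8, comma-separated with a header row; "NA" marks a
# missing value. Schema violations are reported with row/column
# coordinates. Numeric columns are written with 17 significant digits so
# that write followed by read is the identity on doubles.

.chem_columns <- c("id", "name", "smiles", .property_names,
                   paste0(.property_names, "_src"))
.proc_columns <- c("process_id", "product_id", "catalyst_class",
                   "temperature_c", "time_h", "controls",
                   "production_volume")
.part_columns <- c("process_id", "chemical_id", "role")
.emis_columns <- c("process_id", "species_id", "medium",
                   "kg_per_kg_product", "basis")

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  colClasses = "character", check.names = TRUE)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.as_num <- function(df, col, path, min = NULL) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.na(df[[col]]) & is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: row %d, column '%s': not a number ('%s')",
                 basename(path), bad[1], col, df[[col]][bad[1]]),
         call. = FALSE)
  }
  if (!is.null(min)) {
    low <- which(!is.na(x) & x < min)
    if (length(low)) {
      stop(sprintf("%s: row %d, column '%s': value must be >= %g (got %g)",
                   basename(path), low[1], col, min, x[low[1]]),
           call. = FALSE)
    }
  }
  x
}

.check_enum <- function(df, col, levels, path, allow_na = FALSE) {
  x <- df[[col]]
  bad <- which(!(x %in% levels) & !(allow_na & is.na(x)))
  if (length(bad)) {
    stop(sprintf("%s: row %d, column '%s': '%s' is not one of {%s}",
                 basename(path), bad[1], col, x[bad[1]],
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read a chemicals/property table
#'
#' Columns: `id`, `name`, `smiles`, the five property columns of
#' [property_names()], and a parallel `*_src` provenance column per
#' property (measured, database, estimated, trend_filled). `"NA"` marks a
#' missing value. Vapour pressure and water solubility must be
#' non-negative.
#'
#' @param path CSV file path.
#' @return Data frame with numeric property columns.
#' @export
read_chemicals <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("id", "name", "smiles"), path)
  for (p in .property_names) {
    if (!p %in% names(df)) df[[p]] <- NA_character_
    df[[p]] <- .as_num(df, p, path,
                       min = if (p %in% .log_properties) 0 else NULL)
    src <- paste0(p, "_src")
    if (!src %in% names(df)) df[[src]] <- NA_character_
    .check_enum(df, src, .provenance_levels, path, allow_na = TRUE)
  }
  if (anyDuplicated(df$id)) {
    stop(basename(path), ": duplicate chemical id '",
         df$id[duplicated(df$id)][1], "'", call. = FALSE)
  }
  df[, .chem_columns]
}

#' Read process and participant tables
#'
#' @param processes_path CSV with columns `process_id`, `product_id`,
#'   `catalyst_class`, `temperature_c`, `time_h`, `controls`
#'   (semicolon-separated), `production_volume`.
#' @param participants_path CSV with columns `process_id`, `chemical_id`,
#'   `role`.
#' @return Named list of `emitra_process` records.
#' @export
read_processes <- function(processes_path, participants_path) {
  pr <- .read_csv(processes_path)
  .require_columns(pr, .proc_columns, processes_path)
  pa <- .read_csv(participants_path)
  .require_columns(pa, .part_columns, participants_path)
  .check_enum(pr, "catalyst_class", .catalyst_classes, processes_path)
  .check_enum(pa, "role", .roles, participants_path)
  pr$temperature_c <- .as_num(pr, "temperature_c", processes_path)
  pr$time_h <- .as_num(pr, "time_h", processes_path, min = 0)
  pr$production_volume <- .as_num(pr, "production_volume", processes_path,
                                  min = 0)
  orphan <- setdiff(pa$process_id, pr$process_id)
  if (length(orphan)) {
    stop(basename(participants_path), ": participant references unknown ",
         "process '", orphan[1], "'", call. = FALSE)
  }
  procs <- lapply(seq_len(nrow(pr)), function(i) {
    part <- pa[pa$process_id == pr$process_id[i], c("chemical_id", "role"),
               drop = FALSE]
    rownames(part) <- NULL
    ctrl <- pr$controls[i]
    ctrl <- if (is.na(ctrl) || !nzchar(ctrl)) character(0)
            else strsplit(ctrl, ";", fixed = TRUE)[[1]]
    process_record(
      process_id = pr$process_id[i], product_id = pr$product_id[i],
      participants = part, catalyst_class = pr$catalyst_class[i],
      temperature_c = pr$temperature_c[i], time_h = pr$time_h[i],
      controls = trimws(ctrl), production_volume = pr$production_volume[i]
    )
  })
  stats::setNames(procs, pr$process_id)
}

#' Read an emissions table
#'
#' Columns: `process_id`, `species_id`, `medium` (air/water/land),
#' `kg_per_kg_product` (non-negative), `basis`
#' (measured/estimated/read_across).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_emissions <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, .emis_columns, path)
  .check_enum(df, "medium", .media, path)
  .check_enum(df, "basis", .bases, path)
  df$kg_per_kg_product <- .as_num(df, "kg_per_kg_product", path, min = 0)
  df[, .emis_columns]
}

#' Read a SMILES library file
#'
#' One record per line, `SMILES<tab>name`.
#'
#' @param path File path.
#' @return Data frame `id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop(basename(path), ": line ", bad[1],
         ": expected 'SMILES<tab>name'", call. = FALSE)
  }
  data.frame(id = vapply(parts, `[[`, character(1), 2L),
             smiles = vapply(parts, `[[`, character(1), 1L),
             stringsAsFactors = FALSE)
}

#' Read structures from an SDF (V2000) file
#'
#' @param path File path.
#' @return Data frame `id`, `smiles` (canonical).
#' @export
read_sdf_file <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L && nzchar(parts[[i]][2])) parts[[i]][2]
      else sprintf("mol_%d", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
}

## ---- writers --------------------------------------------------------------

.fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

.write_csv <- function(df, path, numeric_cols) {
  out <- df
  for (col in intersect(numeric_cols, names(out))) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Write a chemicals table
#' @param chemicals Data frame as returned by [read_chemicals()].
#' @param path Output CSV path.
#' @export
write_chemicals <- function(chemicals, path) {
  .write_csv(chemicals[, .chem_columns], path, .property_names)
}

#' Write process and participant tables
#' @param processes Named list of `emitra_process` records.
#' @param processes_path,participants_path Output CSV paths.
#' @export
write_processes <- function(processes, processes_path, participants_path) {
  pr <- do.call(rbind, lapply(processes, function(p) {
    data.frame(
      process_id = p$process_id, product_id = p$product_id,
      catalyst_class = p$catalyst_class, temperature_c = p$temperature_c,
      time_h = p$time_h,
      controls = paste(p$controls, collapse = ";"),
      production_volume = p$production_volume, stringsAsFactors = FALSE
    )
  }))
  pa <- do.call(rbind, lapply(processes, function(p) {
    data.frame(process_id = p$process_id,
               chemical_id = p$participants$chemical_id,
               role = p$participants$role, stringsAsFactors = FALSE)
  }))
  rownames(pr) <- rownames(pa) <- NULL
  .write_csv(pr, processes_path,
             c("temperature_c", "time_h", "production_volume"))
  .write_csv(pa, participants_path, character(0))
  invisible(c(processes_path, participants_path))
}

#' Write an emissions table
#' @param emissions Data frame as returned by [read_emissions()].
#' @param path Output CSV path.
#' @export
write_emissions <- function(emissions, path) {
  .write_csv(emissions[, .emis_columns], path, "kg_per_kg_product")
}

#' Read a framework run configuration from YAML
#'
#' Recognized keys: `chemicals`, `processes`, `participants`, `emissions`
#' (paths, resolved relative to the config file), `target_id`,
#' `target_process_id`, `mode`, `factor_rule`, `factor_properties`,
#' `cutoff`, `fingerprint_scheme`, `similarity_thresholds`
#' (`low`/`moderate`), `max_temp_diff_c`, `max_time_ratio`, `descriptor`,
#' `fill_gaps`, `iterate`, `seed`, `output_dir`. Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Configuration list for [run_framework()], tables loaded.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("chemicals", "processes", "participants", "emissions",
             "target_id", "target_process_id", "mode", "factor_rule",
             "factor_properties", "cutoff", "fingerprint_scheme",
             "similarity_thresholds", "max_temp_diff_c", "max_time_ratio",
             "descriptor", "fill_gaps", "iterate", "molar_basis", "seed",
             "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(basename(path), ": unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("config references missing file: ", p,
                              call. = FALSE)
    p
  }
  for (key in c("chemicals", "processes", "participants", "emissions")) {
    cfg[[key]] <- resolve(cfg[[key]])
  }
  cfg$chemicals <- read_chemicals(cfg$chemicals)
  procs <- read_processes(cfg$processes, cfg$participants)
  cfg$processes <- procs
  cfg$participants <- NULL
  cfg$emissions <- read_emissions(cfg$emissions)
  cfg
}

#' Write a framework report to disk
#'
#' Writes `report.json` (estimates, factors, role map, analogue ranking,
#' uncertainty drivers, warnings, step log) and `estimates.tsv` (the
#' estimated emission rows).
#'
#' @param report An `emitra_report` from [run_framework()].
#' @param dir Output directory, created if needed.
#' @return Paths of the files written (invisibly).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "emitra_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  tsv_path <- file.path(dir, "estimates.tsv")
  payload <- list(
    target_id = report$target_id,
    target_process_id = report$target_process_id,
    mode = report$mode,
    grouping = report$grouping,
    factor_rule = report$factor_rule,
    overall_factor = report$overall_factor,
    halted = report$halted,
    halt_reason = report$halt_reason,
    steps = report$steps,
    analogues = report$analogues,
    category = if (!is.null(report$category)) list(
      member_ids = report$category$member_ids,
      shared_feature = report$category$shared_feature,
      valid = report$category$valid
    ),
    gap_summary = if (!is.null(report$gap_report)) list(
      n_missing = report$gap_report$n_missing,
      missing = report$gap_report$missing
    ),
    fills = lapply(report$fills, function(f) {
      list(property = f$property, target_id = f$target_id, value = f$value,
           extrapolated = f$extrapolated)
    }),
    compatibility = report$compatibility,
    role_map = if (!is.null(report$role_map)) report$role_map$map,
    factors = report$factors,
    estimates = if (length(report$estimates)) estimates_table(report$estimates),
    uncertainty = lapply(report$estimates, function(e) {
      list(species_id = e$species_id, grade = e$uncertainty$grade,
           drivers = e$uncertainty$drivers)
    }),
    warnings = report$warnings
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (length(report$estimates)) {
    utils::write.table(estimates_table(report$estimates), tsv_path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(c(json_path, tsv_path))
}
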