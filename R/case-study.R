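# Embedded case study: one-to-one read-across from the cumene process to
# the p-cymene process.
#
# Both chemicals are made by solid-acid-catalyzed alkylation with propylene
# gas (benzene + propylene -> cumene; toluene + propylene -> p-cymene), so
# the processes are directly comparable. The fixture carries the four
# analogous alkylbenzenes with their tabulated physicochemical properties
# (PubChem-sourced, provenance "database"), the two process descriptions,
# and the measured air emissions of the cumene process in kg emitted per kg
# product: benzene 5.9e-06, propylene 7.8e-06, cumene 1.9e-05.

#' Load the embedded cumene / p-cymene case study
#'
#' @return List with `chemicals` (property table for p-cymene, cumene,
#'   1,4-diisopropylbenzene, 1,3,5-triisopropylbenzene and the process
#'   species), `processes` (named list of `emitra_process`), `emissions`
#'   (measured cumene-process air emissions), and the conventional
#'   `target_id` / `target_process_id` of the worked example.
#' @examples
#' cs <- load_case_study()
#' subset(cs$emissions, species_id == "benzene")$kg_per_kg_product  # 5.9e-06
#' @export
load_case_study <- function() {
  dir <- system.file("extdata", "case_study", package = "emitra",
                     mustWork = TRUE)
  list(
    chemicals = read_chemicals(file.path(dir, "chemicals.csv")),
    processes = read_processes(file.path(dir, "processes.csv"),
                               file.path(dir, "participants.csv")),
    emissions = read_emissions(file.path(dir, "emissions.csv")),
    target_id = "p_cymene",
    target_process_id = "p_cymene_process"
  )
}

#' Export the case-study fixture as the standard CSV files
#'
#' Writes `chemicals.csv`, `processes.csv`, `participants.csv` and
#' `emissions.csv` through the package's own writers, so the export
#' round-trips through [read_chemicals()] and friends.
#'
#' @param dir Output directory, created if needed.
#' @return Paths written (invisibly).
#' @export
export_case_study <- function(dir) {
  cs <- load_case_study()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_chemicals(cs$chemicals, file.path(dir, "chemicals.csv")),
    write_processes(cs$processes, file.path(dir, "processes.csv"),
                    file.path(dir, "participants.csv")),
    write_emissions(cs$emissions, file.path(dir, "emissions.csv"))
  )
  invisible(paths)
}
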