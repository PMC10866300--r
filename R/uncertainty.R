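# Uncertainty grading for read-across estimates.
#
# The grading reconstructs the qualitative rule that high-quality data on
# structurally very similar chemicals made in very similar processes yields
# low uncertainty, as an explicit worst-driver-wins scheme over five
# criteria. The numeric similarity thresholds are this package's own and
# are calibrated to the default counted atom-pair Tanimoto scale (whose
# scores run far below the near-1 values produced by the saturating
# substructure-key schemes of online search tools); they are configurable.

.grade_levels <- c("low", "moderate", "high")

#' Grade the uncertainty of a read-across estimate
#'
#' Each driver is rated low, moderate or high and the overall grade is the
#' worst driver, so degrading any single input can never improve the
#' grade:
#' \itemize{
#'   \item structural similarity: at or above `thresholds["low"]` is low,
#'     at or above `thresholds["moderate"]` moderate, below that high;
#'   \item process similarity: compatible without warnings is low, with
#'     warnings moderate, incompatible high;
#'   \item source data basis: measured low, estimated moderate,
#'     read_across high (an estimate built on another estimate inherits
#'     its unreliability);
#'   \item trend-filled properties feeding the factors: at least moderate;
#'   \item trend extrapolation beyond the category range: at least
#'     moderate.
#' }
#'
#' @param similarity Tanimoto similarity between target and source, in
#'   \[0, 1\].
#' @param process_compat Result of [check_process_compatibility()].
#' @param source_basis Basis of the source emission data: `"measured"`,
#'   `"estimated"` or `"read_across"`.
#' @param trend_filled_properties Did any trend-filled property value feed
#'   the read-across factors?
#' @param extrapolated Was a trend evaluated outside the category's
#'   descriptor range?
#' @param thresholds Named numeric vector with elements `low` and
#'   `moderate`: similarity cut points for the structural driver.
#' @return An `emitra_uncertainty`: `grade` and the `drivers` table.
#' @export
grade_uncertainty <- function(similarity, process_compat, source_basis,
                              trend_filled_properties = FALSE,
                              extrapolated = FALSE,
                              thresholds = c(low = 0.5, moderate = 0.25)) {
  stopifnot(is.numeric(similarity), similarity >= 0, similarity <= 1,
            all(c("low", "moderate") %in% names(thresholds)),
            thresholds["low"] >= thresholds["moderate"])
  if (!source_basis %in% .bases) {
    stop("unknown source basis '", source_basis, "'", call. = FALSE)
  }
  drivers <- data.frame(
    criterion = c("structural_similarity", "process_similarity",
                  "source_data_quality", "property_trend_filling",
                  "trend_extrapolation"),
    level = c(
      if (similarity >= thresholds["low"]) "low"
      else if (similarity >= thresholds["moderate"]) "moderate"
      else "high",
      if (!process_compat$compatible) "high"
      else if (length(process_compat$warnings)) "moderate"
      else "low",
      switch(source_basis, measured = "low", estimated = "moderate",
             read_across = "high"),
      if (isTRUE(trend_filled_properties)) "moderate" else "low",
      if (isTRUE(extrapolated)) "moderate" else "low"
    ),
    stringsAsFactors = FALSE
  )
  worst <- max(match(drivers$level, .grade_levels))
  structure(
    list(grade = .grade_levels[worst], drivers = drivers),
    class = "emitra_uncertainty"
  )
}

#' @export
print.emitra_uncertainty <- function(x, ...) {
  cat("<uncertainty>", x$grade, "\n")
  for (i in seq_len(nrow(x$drivers))) {
    cat(sprintf("  %-24s %s\n", x$drivers$criterion[i], x$drivers$level[i]))
  }
  invisible(x)
}
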