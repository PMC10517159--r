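#' Write comparison and scan results as CSV
#'
#' Deterministic, diff-stable CSV writers: all numeric columns are rounded
#' to 6 significant digits so identical runs produce bitwise-identical
#' files.
#'
#' `writeComparisonCSV()` writes a scenario comparison from
#' [runScenario()] (columns `node`, `baseline_ss`, `scenario_ss`, `diff`,
#' `pct_vs_baseline`, `pct_vs_scenario`, `direction`).
#' `writeScanCSV()` writes a scan result from [runScan()] (columns
#' `scan_id`, `axis1_name`, `axis1_value`, `axis2_name`, `axis2_value`,
#' `delta`, `label`). `writeSteadyStateCSV()` writes one solved state
#' (columns `node`, `activity`, `residual`, `converged`).
#'
#' @param result a data.frame from [runScenario()] or [runScan()].
#' @param report a [SteadyStateReport-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeComparisonCSV(runScenario("baseline"), p)
#' @name reporting
NULL

.writeStableCSV <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname reporting
#' @export
writeComparisonCSV <- function(result, path) {
  need <- c("node", "baseline_ss", "scenario_ss", "diff", "pct_vs_baseline",
            "pct_vs_scenario", "direction")
  if (!is.data.frame(result) || !all(need %in% names(result)))
    stop("result must come from runScenario()")
  .writeStableCSV(result[need], path)
}

#' @rdname reporting
#' @export
writeScanCSV <- function(result, path) {
  need <- c("scan_id", "axis1_name", "axis1_value", "axis2_name",
            "axis2_value", "delta", "label")
  if (!is.data.frame(result) || !all(need %in% names(result)))
    stop("result must come from runScan()")
  .writeStableCSV(result[need], path)
}

#' @rdname reporting
#' @export
writeSteadyStateCSV <- function(report, path) {
  stopifnot(is(report, "SteadyStateReport"))
  df <- data.frame(node = names(activities(report)),
                   activity = unname(activities(report)),
                   residual = residual(report),
                   converged = converged(report),
                   stringsAsFactors = FALSE)
  .writeStableCSV(df, path)
}
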