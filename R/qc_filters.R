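#' Quality-control configuration for AHCS visit records
#'
#' Two-stage record exclusion: (1) visits with inadequate airflow are
#' removed, because low airflow means incomplete capture of the animal's
#' breath cloud; (2) visits with a biologically infeasible flux on any
#' present gas channel are removed. Defaults follow common practice for
#' cattle: airflow below 26 L/s is excluded, and ceilings of 20,000 g/d
#' CO2, 15,000 g/d O2 and 500 g/d CH4 mark obvious outliers.
#'
#' Boundary semantics are strict on the removal side: airflow exactly at
#' `airflow_min` is kept, and a flux exactly at its ceiling is kept.
#'
#' @param airflow_min minimum acceptable airflow, L/s.
#' @param co2_max,o2_max,ch4_max flux ceilings, g/d.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(airflow_min = 26, co2_max = 20000, o2_max = 15000,
                      ch4_max = 500) {
  limits <- c(airflow_min = airflow_min, co2_max = co2_max,
              o2_max = o2_max, ch4_max = ch4_max)
  if (any(!is.finite(limits)) || any(limits <= 0)) {
    stop("all QC limits must be strictly positive")
  }
  structure(as.list(limits), class = "qc_config")
}

#' Remove visits with inadequate airflow
#'
#' Retains records with `airflow_lps >= airflow_min`; the boundary value
#' is kept (removal is strictly below the minimum).
#'
#' @param table a [visit_table()]; airflow must be present on every record.
#' @param airflow_min minimum acceptable airflow, L/s.
#' @return list with elements `table` (filtered [visit_table()]) and
#'   `n_removed`.
#' @export
apply_airflow_filter <- function(table, airflow_min = 26) {
  if (anyNA(table$airflow_lps)) stop("airflow missing on some records")
  keep <- table$airflow_lps >= airflow_min
  out <- table[keep, ]
  attr(out, "provenance") <- c(attr(table, "provenance"),
                               sprintf("airflow filter >= %g L/s", airflow_min))
  list(table = out, n_removed = sum(!keep))
}

#' Remove visits with biologically infeasible flux estimates
#'
#' A record is removed when ANY present gas value strictly exceeds its
#' ceiling; equality is kept and missing channels never trigger removal.
#' Negative flux values are retained (no lower bound is imposed) but
#' produce a warning since they usually indicate an instrument fault.
#'
#' @param table a [visit_table()].
#' @param config a [qc_config()].
#' @return list with elements `table` and `n_removed`.
#' @export
apply_flux_limits <- function(table, config = qc_config()) {
  exceeds <- function(x, ceiling) !is.na(x) & x > ceiling
  bad <- exceeds(table$co2_gpd, config$co2_max) |
    exceeds(table$o2_gpd, config$o2_max) |
    exceeds(table$ch4_gpd, config$ch4_max)
  neg <- (!is.na(table$co2_gpd) & table$co2_gpd < 0) |
    (!is.na(table$o2_gpd) & table$o2_gpd < 0) |
    (!is.na(table$ch4_gpd) & table$ch4_gpd < 0)
  if (any(neg)) {
    warning(sum(neg), " record(s) carry negative flux values; retained")
  }
  out <- table[!bad, ]
  attr(out, "provenance") <- c(attr(table, "provenance"),
                               sprintf("flux ceilings CO2<=%g O2<=%g CH4<=%g g/d",
                                       config$co2_max, config$o2_max, config$ch4_max))
  list(table = out, n_removed = sum(bad))
}

#' Run the full two-stage QC pipeline
#'
#' Applies the airflow filter first and the flux ceilings second, counting
#' each stage's removals against that stage's own input, so a record that
#' violates both rules is claimed by the airflow stage.
#'
#' @param table a [visit_table()].
#' @param config a [qc_config()].
#' @return list with elements `table` (the QC-passed [visit_table()]) and
#'   `report` (a `qc_report`: `n_input`, `n_removed_airflow`,
#'   `n_removed_flux`, `n_output`).
#' @export
run_qc <- function(table, config = qc_config()) {
  n_input <- nrow(table)
  step1 <- apply_airflow_filter(table, config$airflow_min)
  step2 <- apply_flux_limits(step1$table, config)
  report <- structure(
    list(n_input = n_input,
         n_removed_airflow = step1$n_removed,
         n_removed_flux = step2$n_removed,
         n_output = nrow(step2$table)),
    class = "qc_report"
  )
  stopifnot(report$n_output ==
              report$n_input - report$n_removed_airflow - report$n_removed_flux)
  list(table = step2$table, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "in;",
      x$n_removed_airflow, "removed (airflow);",
      x$n_removed_flux, "removed (flux ceilings);",
      x$n_output, "out\n")
  invisible(x)
}

#' Serialise a QC report to JSON
#'
#' @param report a `qc_report` from [run_qc()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
qc_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
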