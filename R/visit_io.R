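#' Construct a visit table from a data frame
#'
#' A visit table holds one row per AHCS spot sample: animal and experiment
#' identifiers, the visit start timestamp (naive local clock time, no time
#' zone semantics), the visit duration in minutes, airflow in L/s, and the
#' three gas fluxes (CO2, O2, CH4) in g/d. Gas values may be missing per
#' channel; a record then simply does not participate in analyses of the
#' gases it lacks.
#'
#' @param df data frame with columns `animal_id`, `experiment_id`,
#'   `start_time` (POSIXct or ISO 8601 character), `duration_min`,
#'   `airflow_lps`, `co2_gpd`, `o2_gpd`, `ch4_gpd`.
#' @param provenance character vector of free-text notes recording where
#'   the table came from and which filters have been applied.
#' @return A tibble of class `visit_table` with a `provenance` attribute.
#' @export
visit_table <- function(df, provenance = character()) {
  missing_cols <- setdiff(VISIT_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("visit table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df)[VISIT_COLS]
  if (is.character(df$start_time)) {
    df$start_time <- parse_visit_time(df$start_time)
  }
  if (anyNA(df$start_time)) stop("unparseable start_time values")
  if (any(!is.finite(df$duration_min) | df$duration_min <= 0)) {
    stop("all visit durations must be positive")
  }
  if (any(is.finite(df$airflow_lps) & df$airflow_lps < 0)) {
    stop("airflow must be nonnegative")
  }
  # an animal belongs to exactly one experiment
  pairs <- unique(df[c("animal_id", "experiment_id")])
  if (anyDuplicated(pairs$animal_id)) {
    stop("animal_id assigned to more than one experiment_id")
  }
  structure(df, class = c("visit_table", class(df)), provenance = provenance)
}

#' @export
print.visit_table <- function(x, ...) {
  cat("<visit_table> ", nrow(x), " visits, ",
      length(unique(x$animal_id)), " animals, ",
      length(unique(x$experiment_id)), " experiments\n", sep = "")
  prov <- attr(x, "provenance")
  if (length(prov)) cat("provenance: ", paste(prov, collapse = "; "), "\n", sep = "")
  NextMethod()
}

# Timestamps are naive local clock time; they are stored as POSIXct in UTC
# purely so arithmetic is DST-free.
parse_visit_time <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in formats) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], format = f, tz = "UTC"), tz = "UTC")
  }
  out
}

# Clock hour-of-day in [0, 24).
hour_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Read a delimited AHCS visit table
#'
#' Reads a CSV export of per-visit records. Rows with an unparseable
#' timestamp or a nonpositive duration are rejected with per-row
#' diagnostics (attached as the `diagnostics` attribute and summarised in
#' a warning), never silently dropped.
#'
#' @param path path to a CSV file with a header row.
#' @param schema optional named character vector mapping canonical column
#'   names (see [visit_table()]) to the names used in the file, for vendor
#'   exports with a different dialect, e.g.
#'   `c(animal_id = "RFID", duration_min = "GoodDataDuration")`.
#' @return A [visit_table()]; rejected rows are described in
#'   `attr(x, "diagnostics")` (a tibble with `row` and `problem` columns).
#' @export
read_visit_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(raw))
    if (length(bad)) stop("mapped columns absent from file: ", paste(bad, collapse = ", "))
    for (std in names(schema)) names(raw)[names(raw) == schema[[std]]] <- std
  }
  missing_cols <- setdiff(VISIT_COLS, names(raw))
  if (length(missing_cols)) {
    stop("file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  start <- suppressWarnings(parse_visit_time(raw$start_time))
  dur <- suppressWarnings(as.numeric(raw$duration_min))
  problems <- character(nrow(raw))
  problems[is.na(start)] <- "unparseable start_time"
  problems[!is.na(start) & (is.na(dur) | dur <= 0)] <- "nonpositive or missing duration"
  keep <- problems == ""
  if (!any(keep)) stop("no valid rows in ", path)
  df <- tibble::tibble(
    animal_id = raw$animal_id[keep],
    experiment_id = raw$experiment_id[keep],
    start_time = start[keep],
    duration_min = dur[keep],
    airflow_lps = suppressWarnings(as.numeric(raw$airflow_lps[keep])),
    co2_gpd = suppressWarnings(as.numeric(raw$co2_gpd[keep])),
    o2_gpd = suppressWarnings(as.numeric(raw$o2_gpd[keep])),
    ch4_gpd = suppressWarnings(as.numeric(raw$ch4_gpd[keep]))
  )
  diagnostics <- tibble::tibble(row = which(!keep), problem = problems[!keep])
  if (nrow(diagnostics) > 0) {
    warning(nrow(diagnostics), " row(s) rejected while reading ", path,
            "; see attr(x, 'diagnostics')")
  }
  out <- visit_table(df, provenance = paste0("read from ", path))
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Write a visit table to CSV
#'
#' Writes a header row, ISO 8601 timestamps, and empty fields for missing
#' gas values, so that [read_visit_table()] round-trips the table.
#'
#' @param table a [visit_table()]; must be nonempty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_visit_table <- function(table, path) {
  if (nrow(table) == 0) stop("refusing to write an empty visit table")
  out <- tibble::as_tibble(table)
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Per-animal visitation summary
#'
#' Summarises visitation behaviour per animal: visit count, observation
#' span, visits per day, and the mean and SD of visit duration.
#' `observation_days` is the inclusive calendar-day span, (date of last
#' visit − date of first visit) + 1, and `visits_per_day` is
#' `n_visits / observation_days`.
#'
#' @param table a nonempty [visit_table()].
#' @return tibble with one row per animal: `animal_id`, `experiment_id`,
#'   `n_visits`, `observation_days`, `visits_per_day`, `duration_mean`,
#'   `duration_sd` (`NA` for a single visit).
#' @export
per_animal_summary <- function(table) {
  if (nrow(table) == 0) stop("empty visit table")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$animal_id, .data$experiment_id),
    n_visits = dplyr::n(),
    observation_days = as.numeric(
      as.Date(max(.data$start_time)) - as.Date(min(.data$start_time))) + 1,
    visits_per_day = .data$n_visits / .data$observation_days,
    duration_mean = mean(.data$duration_min),
    duration_sd = sd(.data$duration_min),
    .groups = "drop"
  )
}
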