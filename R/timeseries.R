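# Observation tables: the tabular interface between the simulator and the
# EDM layer. A time series table is a tibble with a strictly consecutive
# integer `time` column plus named numeric series; simulator output carries
# the columns Quiet, Active, Jailed, Legitimacy, Propaganda.

ts_columns <- c("time", "Quiet", "Active", "Jailed", "Legitimacy", "Propaganda")

# Structural validation shared by the reader and the simulator output.
validate_timeseries <- function(table, required = ts_columns) {
  if (!is.data.frame(table)) abort_format("time series must be a data frame")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort_format(sprintf("missing required column%s: %s",
                         if (length(missing) > 1) "s" else "",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(table) == 0) abort_format("table has a header but no rows")
  tm <- table$time
  if (anyNA(tm)) abort_format("time column contains missing values")
  if (any(tm != as.integer(tm))) abort_format("time column must be integer steps")
  bad <- which(diff(tm) != 1)
  if (length(bad) > 0) {
    abort_format(sprintf(
      "time steps must be consecutive with no gaps or duplicates (first violation at row %d)",
      bad[1] + 1))
  }
  for (col in setdiff(required, "time")) {
    if (!is.numeric(table[[col]])) {
      abort_format(sprintf("column %s must be numeric", col))
    }
  }
  if ("Legitimacy" %in% names(table)) {
    L <- table$Legitimacy
    if (any(!is.na(L) & (L <= 0 | L > 1))) {
      abort_format("Legitimacy values must lie in (0, 1]")
    }
  }
  if ("Propaganda" %in% names(table)) {
    P <- table$Propaganda
    if (any(!is.na(P) & (P < 0 | P > 1))) {
      abort_format("Propaganda values must lie in [0, 1]")
    }
  }
  invisible(table)
}

#' Read an observation time series from CSV
#'
#' Expects the comma-separated dialect written by [write_timeseries()]: a
#' header row `time,Quiet,Active,Jailed,Legitimacy,Propaganda`, integer time
#' steps with no gaps or duplicates, and empty fields for missing values.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the observation columns.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  tab <- readr::read_csv(path, col_types = readr::cols(
    time = readr::col_integer(), .default = readr::col_double()),
    na = c("", "NA"), progress = FALSE)
  validate_timeseries(tab)
  tab
}

#' Write an observation time series to CSV
#'
#' @param table Observation tibble (see [read_timeseries()] for the dialect).
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_timeseries <- function(table, path) {
  validate_timeseries(table)
  readr::write_csv(table[ts_columns], path, na = "", progress = FALSE)
  invisible(table)
}
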