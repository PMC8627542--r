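.incubation_cols <- c("time_h", "replicate", "nh4_umol_L", "no2_umol_L",
                      "no3_umol_L")

#' Validate an incubation series table
#'
#' Checks the long-format incubation contract: required columns present,
#' concentrations finite and non-negative, no duplicated (time, replicate)
#' rows; rows are returned sorted by time then replicate. Row-level
#' diagnostics name the offending rows.
#'
#' @param series a data frame with columns `time_h`, `replicate`,
#'   `nh4_umol_L`, `no2_umol_L`, `no3_umol_L` (a missing `replicate` column is
#'   filled with `"R1"`).
#' @return the validated, sorted data frame.
#' @export
validate_incubation <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0L)
    stop("incubation series must be a non-empty data frame")
  if (!"replicate" %in% names(series)) series$replicate <- "R1"
  missing_cols <- setdiff(.incubation_cols, names(series))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  series$replicate <- as.character(series$replicate)
  for (cc in c("time_h", "nh4_umol_L", "no2_umol_L", "no3_umol_L")) {
    v <- series[[cc]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("column '", cc, "' must be finite numeric (rows: ",
           paste(utils::head(which(!is.finite(as.numeric(v))), 5), collapse = ", "),
           ")")
  }
  for (cc in c("nh4_umol_L", "no2_umol_L", "no3_umol_L")) {
    bad <- which(series[[cc]] < 0)
    if (length(bad) > 0L)
      stop("negative concentration in '", cc, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(series$time_h, series$replicate)
  if (anyDuplicated(key))
    stop("duplicate (time, replicate) row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  series <- series[order(series$time_h, series$replicate), .incubation_cols]
  row.names(series) <- NULL
  series
}

#' Read an incubation time series from CSV
#'
#' Expects the package's fixed dialect: comma-separated UTF-8 with a header
#' row `time_h,replicate,nh4_umol_L,no2_umol_L,no3_umol_L`, time in hours and
#' concentrations in µmol L⁻¹. The table is validated with
#' [validate_incubation()].
#'
#' @param path path to a CSV file.
#' @return validated incubation data frame.
#' @export
read_incubation_csv <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_incubation(df)
}

#' Write an incubation time series to CSV
#'
#' @param series incubation data frame (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incubation_csv <- function(series, path) {
  series <- validate_incubation(series)
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a simulator configuration as a plain key-value file
#'
#' One `key = value` pair per line; readable by eye, by the CLI and by
#' [read_sim_config()].
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `path` (writer) / a [sim_config()] (reader), invisibly for the
#'   writer.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lines <- sprintf("%s = %s", names(config),
                   vapply(config, function(v) format(v, digits = 15), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  unknown <- setdiff(keys, names(formals(sim_config)))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, as.list(stats::setNames(vals, keys)))
}
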