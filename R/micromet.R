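#' Micrometeorological time series
#'
#' A `micromet_series` is a data frame of timestamped weather observations
#' with the canonical columns `timestamp` (POSIXct, UTC), `ta_c` (air
#' temperature, degrees C), `rh_pct` (relative humidity, %), `ws_ms` (wind
#' speed, m/s), `sr_wm2` (global horizontal solar radiation, W/m2), and the
#' optional columns `tg_c` (black-globe temperature, C), `ts_c`
#' (ground-surface temperature, C) and `solar_elev_deg` (solar elevation
#' above the horizon, degrees).  Attributes carry the nominal sampling
#' interval in seconds and free-form provenance metadata.
#'
#' Validation is strict: humidities outside \[0, 100\], negative wind or
#' radiation, air temperatures outside \[-60, 60\] and non-increasing or
#' duplicated timestamps are errors, reported with row numbers.  Optional
#' columns must be either absent or present for every record; downstream
#' code that needs a missing optional fails loudly rather than imputing.
#'
#' @param data data frame with at least the mandatory canonical columns
#'   (case-insensitive names).
#' @param interval_s nominal sampling interval, seconds; inferred from the
#'   median timestamp difference when `NULL`.
#' @param metadata named character vector or list of provenance strings.
#' @return A validated `micromet_series` (also a `data.frame`).
#' @examples
#' df <- data.frame(
#'   timestamp = as.POSIXct("2020-05-19 18:30", tz = "UTC") + c(0, 10, 20),
#'   ta_c = c(33.1, 33.2, 33.3), rh_pct = 48, ws_ms = 2.4, sr_wm2 = 880
#' )
#' s <- micromet_series(df)
#' summary(s)
#' @export
micromet_series <- function(data, interval_s = NULL, metadata = list()) {
  stopifnot(is.data.frame(data))
  names(data) <- tolower(names(data))
  mandatory <- c("timestamp", "ta_c", "rh_pct", "ws_ms", "sr_wm2")
  optional  <- c("tg_c", "ts_c", "solar_elev_deg")
  miss <- setdiff(mandatory, names(data))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(data), c(mandatory, optional))
  if (length(extra))
    stop("unrecognized column(s): ", paste(extra, collapse = ", "))
  if (nrow(data) == 0L) stop("series must be non-empty")

  if (!inherits(data$timestamp, "POSIXct")) {
    ts <- as.POSIXct(data$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    if (anyNA(ts))
      stop("unparseable timestamp(s) at row(s): ",
           paste(which(is.na(ts)), collapse = ", "))
    data$timestamp <- ts
  }
  attr(data$timestamp, "tzone") <- "UTC"

  for (col in setdiff(c(mandatory, optional), "timestamp")) {
    if (!col %in% names(data)) next
    v <- data[[col]]
    if (all(is.na(v)) && col %in% optional) { data[[col]] <- NULL; next }
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v))
    if (length(bad))
      stop("column '", col, "': non-numeric value(s) at row(s): ",
           paste(bad, collapse = ", "))
    if (anyNA(vn))
      stop("column '", col, "': missing value(s) at row(s): ",
           paste(which(is.na(vn)), collapse = ", "),
           " (optional columns must be all-present or all-absent)")
    data[[col]] <- vn
  }

  .check_range <- function(col, lo, hi) {
    v <- data[[col]]
    bad <- which(v < lo | v > hi)
    if (length(bad))
      stop("column '", col, "': value out of [", lo, ", ", hi,
           "] at row(s): ", paste(bad, collapse = ", "))
  }
  .check_range("ta_c", -60, 60)
  .check_range("rh_pct", 0, 100)
  .check_range("ws_ms", 0, Inf)
  .check_range("sr_wm2", 0, Inf)

  dt <- diff(as.numeric(data$timestamp))
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing; violation before row(s): ",
         paste(which(dt <= 0) + 1L, collapse = ", "))

  if (is.null(interval_s))
    interval_s <- if (length(dt)) stats::median(dt) else 1
  if (!is.numeric(interval_s) || interval_s <= 0)
    stop("interval_s must be > 0")

  rownames(data) <- NULL
  structure(data,
            interval_s = as.numeric(interval_s),
            metadata = metadata,
            class = c("micromet_series", "data.frame"))
}

#' Test and query helpers for micromet series
#' @param x object.
#' @return `is_micromet_series` returns a logical; `series_interval` the
#'   nominal sampling interval in seconds.
#' @export
is_micromet_series <- function(x) inherits(x, "micromet_series")

#' @rdname is_micromet_series
#' @export
series_interval <- function(x) attr(x, "interval_s")

#' Read a micrometeorological CSV
#'
#' Reads a CSV with the canonical header
#' `timestamp,ta_c,rh_pct,ws_ms,sr_wm2,tg_c,ts_c` (column names matched
#' case-insensitively; optional columns may be absent or empty).  The
#' `logger` dialect additionally tolerates one free-form preamble line
#' before the header and a unit row immediately after it (a first data row
#' whose timestamp cell does not parse is taken to be units and dropped).
#'
#' @param path path to the CSV file.
#' @param dialect `"generic"` (plain CSV) or `"logger"`.
#' @param interval_s,metadata passed to [micromet_series()].
#' @return A validated [micromet_series()].
#' @seealso [write_micromet()]
#' @export
read_micromet <- function(path, dialect = c("generic", "logger"),
                          interval_s = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  skip <- 0L
  if (dialect == "logger") {
    first <- readLines(path, n = 1L)
    if (!grepl("timestamp", first, ignore.case = TRUE)) skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!"timestamp" %in% names(df))
    stop("missing mandatory column(s): timestamp")
  if (dialect == "logger" && nrow(df) > 0) {
    ts1 <- tryCatch(
      as.POSIXct(df$timestamp[1], tz = "UTC",
        tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                       "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")),
      error = function(e) NA)
    if (is.na(ts1)) df <- df[-1L, , drop = FALSE]
  }
  # empty optional cells read as NA; all-NA optionals are dropped in the
  # constructor
  micromet_series(df, interval_s = interval_s, metadata = metadata)
}

#' Write a micrometeorological series to CSV
#'
#' Writes the canonical header and ISO 8601 timestamps (UTC); optional
#' columns that are absent from the series are omitted, never imputed.
#'
#' @param series a [micromet_series()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [read_micromet()]
#' @export
write_micromet <- function(series, path) {
  stopifnot(is_micromet_series(series))
  out <- as.data.frame(series)
  out$timestamp <- format(series$timestamp, "%Y-%m-%dT%H:%M:%S",
                          tz = "UTC")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Per-variable max/min/mean summary
#'
#' Summarizes one or more variables of a series the way field campaigns
#' report session aggregates: maximum, minimum and arithmetic mean, rounded
#' to one decimal.
#'
#' @param series a [micromet_series()] (or any data frame).
#' @param variables character vector of column names to summarize; default
#'   all numeric columns.
#' @param digits rounding for the reported values (default 1); use `NA` for
#'   full precision.
#' @return data frame with columns `variable`, `max`, `min`, `mean`.
#' @examples
#' s <- generate_micromet(may_session_spec(seed = 1))
#' summarize_series(s, c("ta_c", "rh_pct"))
#' @export
summarize_series <- function(series, variables = NULL, digits = 1) {
  df <- as.data.frame(series)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  if (is.null(variables)) variables <- num
  unknown <- setdiff(variables, names(df))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  notnum <- setdiff(variables, num)
  if (length(notnum))
    stop("non-numeric variable(s): ", paste(notnum, collapse = ", "))
  res <- data.frame(
    variable = variables,
    max  = vapply(variables, function(v) max(df[[v]]), numeric(1)),
    min  = vapply(variables, function(v) min(df[[v]]), numeric(1)),
    mean = vapply(variables, function(v) mean(df[[v]]), numeric(1)),
    row.names = NULL
  )
  if (!is.na(digits))
    res[c("max", "min", "mean")] <- lapply(res[c("max", "min", "mean")],
                                           round, digits = digits)
  res
}

#' @export
print.micromet_series <- function(x, ...) {
  cat("<micromet_series> ", nrow(x), " records @ ",
      attr(x, "interval_s"), " s (",
      format(min(x$timestamp), "%Y-%m-%d %H:%M", tz = "UTC"), " .. ",
      format(max(x$timestamp), "%H:%M", tz = "UTC"), " UTC)\n", sep = "")
  opt <- intersect(c("tg_c", "ts_c", "solar_elev_deg"), names(x))
  if (length(opt)) cat("optional columns:", paste(opt, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 5), ...)
  if (nrow(x) > 5) cat("... (", nrow(x) - 5, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
summary.micromet_series <- function(object, ...) {
  summarize_series(object, ...)
}
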