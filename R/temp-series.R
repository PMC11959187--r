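#' Timestamped temperature series
#'
#' A `temp_series` is a data frame with columns `datetime` (POSIXct, strictly
#' increasing), `temp_c` (finite numeric, degrees Celsius) and `source`
#' (either `"recorded"` or `"imputed"`), carrying the site identifier as an
#' attribute. It is the common currency of the package: logger reads, weather
#' station series, model predictions and gap-filled series all use it.
#'
#' @param datetime POSIXct vector of observation times. Stored in whatever
#'   timezone it arrives in; clock-time operations (e.g. daytime means) use
#'   the civil time of that zone.
#' @param temp_c numeric vector of temperatures in degrees Celsius.
#' @param source character vector (recycled) with values `"recorded"` or
#'   `"imputed"`, one per point.
#' @param site_id single character label for the site.
#' @return An object of class `temp_series`.
#' @examples
#' ts <- temp_series(as.POSIXct("2021-05-01 00:00", tz = "UTC") + 3600 * 0:5,
#'                   c(10, 10.5, 11, 11.2, 11.1, 10.9), site_id = "demo")
#' ts
#' @export
temp_series <- function(datetime, temp_c, source = "recorded",
                        site_id = "site") {
  if (!inherits(datetime, "POSIXct")) {
    stop("`datetime` must be POSIXct", call. = FALSE)
  }
  n <- length(datetime)
  if (length(temp_c) != n) {
    stop("`datetime` and `temp_c` must have equal length", call. = FALSE)
  }
  source <- rep_len(as.character(source), n)
  if (n && !all(source %in% c("recorded", "imputed"))) {
    stop("`source` must be 'recorded' or 'imputed'", call. = FALSE)
  }
  if (n && any(!is.finite(temp_c))) {
    stop("temperatures must be finite; first bad index: ",
         which(!is.finite(temp_c))[1], call. = FALSE)
  }
  if (n > 1 && any(diff(as.numeric(datetime)) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(datetime = datetime, temp_c = as.numeric(temp_c),
                    source = source, stringsAsFactors = FALSE)
  attr(out, "site_id") <- as.character(site_id)
  class(out) <- c("temp_series", "data.frame")
  out
}

#' @export
print.temp_series <- function(x, ...) {
  cat(sprintf("<temp_series> site '%s': %d points", site_id(x), nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", %s to %s, %.1f%% recorded",
                format(x$datetime[1]), format(x$datetime[nrow(x)]),
                100 * mean(x$source == "recorded")))
  }
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Site identifier of a temperature series
#' @param x a `temp_series`.
#' @return character scalar.
#' @export
site_id <- function(x) attr(x, "site_id") %||% "site"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild a temp_series from a plain subset, keeping attributes.
ts_rebuild <- function(df, site) {
  temp_series(df$datetime, df$temp_c, df$source, site_id = site)
}

#' Read a temperature series from CSV
#'
#' Parses a logger or weather-station CSV into a [temp_series]. Rows are
#' sorted by time; duplicated timestamps are collapsed to their mean value
#' (a point is `recorded` if any duplicate was) and the number of collapsed
#' duplicates is returned in the `n_duplicates` attribute.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping internal names to file column
#'   names; needs `datetime` and `temp_c`, optionally `source`.
#' @param timezone timezone for parsing timestamps (local civil time of the
#'   site; defaults to `"UTC"`).
#' @param site_id site label; defaults to the file name without extension.
#' @return A [temp_series] with attribute `n_duplicates`.
#' @export
read_series <- function(path,
                        schema = c(datetime = "datetime", temp_c = "temp_c"),
                        timezone = "UTC",
                        site_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- schema[c("datetime", "temp_c")]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- parse_timestamps(raw[[need[["datetime"]]]], timezone, path)
  temp <- suppressWarnings(as.numeric(raw[[need[["temp_c"]]]]))
  if (anyNA(temp)) {
    stop("non-numeric temperature in ", path, " at row ",
         which(is.na(temp))[1], call. = FALSE)
  }
  src <- if (!is.na(schema["source"]) && schema[["source"]] %in% names(raw)) {
    as.character(raw[[schema[["source"]]]])
  } else rep("recorded", length(temp))

  ord <- order(dt)
  dt <- dt[ord]; temp <- temp[ord]; src <- src[ord]
  key <- as.numeric(dt)
  n_dup <- sum(duplicated(key))
  if (n_dup > 0) {
    grp <- match(key, unique(key))
    temp <- as.numeric(tapply(temp, grp, mean))
    src <- as.character(tapply(src, grp, function(s)
      if (any(s == "recorded")) "recorded" else "imputed"))
    dt <- dt[!duplicated(key)]
  }
  if (is.null(site_id)) site_id <- sub("\\.[^.]*$", "", basename(path))
  out <- temp_series(dt, temp, src, site_id = site_id)
  attr(out, "n_duplicates") <- n_dup
  out
}

parse_timestamps <- function(x, timezone, path) {
  dt <- as.POSIXct(x, tz = timezone,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M:%OS",
                                  "%Y/%m/%d %H:%M", "%Y-%m-%d"),
                   optional = TRUE)
  if (anyNA(dt)) {
    stop("unparseable timestamp in ", path, " at row ", which(is.na(dt))[1],
         ": '", x[which(is.na(dt))[1]], "'", call. = FALSE)
  }
  dt
}

#' Write a temperature series to CSV
#'
#' Writes `site,datetime,temp_c,source` with ISO-8601 timestamps; the inverse
#' of [read_series()] under the default schema.
#'
#' @param series a [temp_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  df <- data.frame(site = site_id(series),
                   datetime = format(series$datetime, "%Y-%m-%dT%H:%M:%S"),
                   temp_c = series$temp_c,
                   source = series$source)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate a series to hourly means
#'
#' Points are grouped by the hour containing them; each present hour gets the
#' unweighted mean of its points, labelled at the hour start. Hours with no
#' observations are simply absent (imputation is a separate, model-based
#' step). An hour is flagged `recorded` if any contributing point was
#' recorded. Idempotent on already-hourly input.
#'
#' @param series a [temp_series].
#' @return An hourly [temp_series].
#' @export
resample_hourly <- function(series) {
  if (nrow(series) == 0) return(series)
  tz <- attr(series$datetime, "tzone") %||% "UTC"
  hour <- as.POSIXct(floor(as.numeric(series$datetime) / 3600) * 3600,
                     tz = tz, origin = "1970-01-01")
  grp <- match(as.numeric(hour), unique(as.numeric(hour)))
  temp <- as.numeric(tapply(series$temp_c, grp, mean))
  src <- as.character(tapply(series$source, grp, function(s)
    if (any(s == "recorded")) "recorded" else "imputed"))
  temp_series(hour[!duplicated(grp)], temp, src, site_id = site_id(series))
}

#' Restrict a series to a half-open time window
#'
#' Keeps points with `start <= datetime < end`. An empty result is allowed.
#'
#' @param series a [temp_series].
#' @param start,end POSIXct window bounds, `start < end`.
#' @return A [temp_series].
#' @export
restrict_window <- function(series, start, end) {
  if (!(start < end)) stop("`start` must precede `end`", call. = FALSE)
  keep <- series$datetime >= start & series$datetime < end
  ts_rebuild(as.data.frame(series)[keep, , drop = FALSE], site_id(series))
}
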