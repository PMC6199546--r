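#' Construct a weather series
#'
#' A weather series is a data.frame with one row per day of the 1 March --
#' 1 October season and columns \code{date, tmax, tmin, rhum, wind, srad,
#' precip}, carrying the site id, the realization label (\code{"OB"} for
#' the observed truth, \code{"CR"} for the control run, \code{"M01"}... for
#' ensemble members) and the site latitude as attributes.
#'
#' @param days data.frame with the seven daily columns.
#' @param site_id Site identifier.
#' @param realization Realization label.
#' @param latitude Site latitude in decimal degrees (used downstream for
#'   extraterrestrial radiation).
#' @return An object of class \code{weather_series} (inherits data.frame).
#' @export
weather_series <- function(days, site_id, realization, latitude) {
  ws <- structure(as.data.frame(days),
                  site_id = site_id,
                  realization = realization,
                  latitude = latitude,
                  class = c("weather_series", "data.frame"))
  validate_weather_series(ws)
}

#' Validate a weather series
#'
#' Checks the physical invariants: strictly increasing gap-free daily dates,
#' tmax >= tmin, precip >= 0, relative humidity in \[0, 100\], srad >= 0.
#'
#' @param ws A \code{weather_series}.
#' @return The series, invisibly, if valid; otherwise an error.
#' @export
validate_weather_series <- function(ws) {
  need <- c("date", "tmax", "tmin", "rhum", "wind", "srad", "precip")
  miss <- setdiff(need, names(ws))
  if (length(miss)) stop("weather series lacks columns: ",
                         paste(miss, collapse = ", "))
  d <- as.Date(ws$date)
  if (nrow(ws) > 1 && any(diff(as.integer(d)) != 1L))
    stop("dates must be strictly increasing daily with no gaps")
  if (any(ws$tmax < ws$tmin)) stop("tmax < tmin found")
  if (any(ws$precip < 0)) stop("negative precipitation found")
  if (any(ws$rhum < 0 | ws$rhum > 100)) stop("rhum outside [0, 100] found")
  if (any(ws$srad < 0)) stop("negative srad found")
  if (any(ws$wind < 0)) stop("negative wind found")
  invisible(ws)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> site %s, realization %s, %d days (%s .. %s)\n",
              attr(x, "site_id"), attr(x, "realization"), nrow(x),
              format(min(as.Date(x$date))), format(max(as.Date(x$date)))))
  cat(sprintf("  season precip %.1f mm, mean tmax %.1f C, mean srad %.1f MJ/m2\n",
              sum(x$precip), mean(x$tmax), mean(x$srad)))
  invisible(x)
}

# Fast internal constructor: builds the classed data.frame directly from
# equal-length columns, skipping data.frame()'s overhead and validation.
# Callers must guarantee the invariants hold by construction.
new_weather_series <- function(date, tmax, tmin, rhum, wind, srad, precip,
                               site_id, realization, latitude) {
  structure(list(date = date, tmax = tmax, tmin = tmin, rhum = rhum,
                 wind = wind, srad = srad, precip = precip),
            row.names = c(NA_integer_, -length(date)),
            site_id = site_id, realization = realization,
            latitude = latitude,
            class = c("weather_series", "data.frame"))
}

# Daily dates of the fixed 1 March -- 1 October forecast window. The window
# always holds 215 days; 29 February can never fall inside it, so leap years
# need no special case.
season_dates <- function(year) {
  seq(as.Date(sprintf("%d-03-01", year)), as.Date(sprintf("%d-10-01", year)),
      by = "day")
}

#' Write a weather series to CSV
#'
#' Writes the schema \code{date,tmax,tmin,rhum,wind,srad,precip} with an
#' extra \code{realization} column and ISO-8601 dates.
#'
#' @param ws A \code{weather_series}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_weather_csv <- function(ws, path) {
  out <- data.frame(date = format(as.Date(ws$date)),
                    tmax = ws$tmax, tmin = ws$tmin, rhum = ws$rhum,
                    wind = ws$wind, srad = ws$srad, precip = ws$precip,
                    realization = attr(ws, "realization"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weather series from CSV
#'
#' @param path CSV path with the schema written by
#'   \code{\link{write_weather_csv}} (the \code{realization} column is
#'   optional and may instead be supplied as an argument).
#' @param site_id Site identifier to attach.
#' @param latitude Site latitude to attach.
#' @param realization Realization label; defaults to the file's
#'   \code{realization} column.
#' @return A validated \code{weather_series}.
#' @export
read_weather_csv <- function(path, site_id, latitude, realization = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(realization)) {
    if (is.null(df$realization))
      stop("no realization column in ", path, " and none supplied")
    realization <- df$realization[1]
  }
  df$realization <- NULL
  df$date <- as.Date(df$date)
  weather_series(df, site_id = site_id, realization = realization,
                 latitude = latitude)
}
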