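#' Daily extraterrestrial radiation
#'
#' Computes daily extraterrestrial (top-of-atmosphere) solar radiation from
#' the standard solar-geometry closed form: inverse relative Earth--Sun
#' distance, solar declination and sunset hour angle.
#'
#' @param doy Day of year, 1--366. Vectorised.
#' @param latitude Latitude in decimal degrees; must lie strictly between
#'   -66 and 66 (polar day/night are not supported).
#' @return Extraterrestrial radiation in MJ m-2 day-1 (strictly positive).
#' @export
#' @examples
#' extraterrestrial_radiation(246, -20) # ~32.2 MJ/m2/day
extraterrestrial_radiation <- function(doy, latitude) {
  if (any(doy < 1 | doy > 366)) stop("doy must be in 1..366")
  if (any(latitude <= -66 | latitude >= 66))
    stop("latitude must lie strictly between -66 and 66 degrees")
  gsc <- 0.0820 # solar constant, MJ m-2 min-1
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(clip(-tan(phi) * tan(decl), -1, 1))
  24 * 60 / pi * gsc * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Global radiation from sunshine fraction (Angstrom--Prescott)
#'
#' Estimates incoming global (shortwave) radiation from relative sunshine
#' duration via the Angstrom--Prescott linear relation
#' \code{Rs = (a + b * n/N) * Ra}.
#'
#' @param sunshine_fraction Relative sunshine duration n/N in \[0, 1\].
#'   Vectorised.
#' @param ra Extraterrestrial radiation, MJ m-2 day-1 (>= 0).
#' @param a,b Regression coefficients; defaults a = 0.25, b = 0.50 are the
#'   widely used values where no local calibration exists. Must satisfy
#'   a >= 0, b >= 0, a + b <= 1.
#' @return Global radiation in MJ m-2 day-1.
#' @export
#' @examples
#' prescott_radiation(0.5, 40) # 20
prescott_radiation <- function(sunshine_fraction, ra, a = 0.25, b = 0.50) {
  if (any(sunshine_fraction < 0 | sunshine_fraction > 1))
    stop("sunshine_fraction must be in [0, 1]")
  if (any(ra < 0)) stop("ra must be >= 0")
  stopifnot(a >= 0, b >= 0, a + b <= 1)
  (a + b * sunshine_fraction) * ra
}

#' Hargreaves reference evapotranspiration
#'
#' Temperature/radiation formulation of daily reference crop
#' evapotranspiration:
#' \code{ET0 = 0.0023 * (Tmean + 17.8) * sqrt(Tmax - Tmin) * 0.408 * Ra},
#' floored at zero. Used by the crop surrogate, which guarantees only
#' temperature and radiation realism of its weather inputs.
#'
#' @param tmax,tmin Daily maximum/minimum air temperature, degrees C;
#'   tmax >= tmin required. Vectorised.
#' @param ra Extraterrestrial radiation, MJ m-2 day-1 (>= 0).
#' @return Reference evapotranspiration, mm day-1 (>= 0).
#' @export
#' @examples
#' hargreaves_et0(30, 18, 40) # ~5.44 mm/day
hargreaves_et0 <- function(tmax, tmin, ra) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  if (any(ra < 0)) stop("ra must be >= 0")
  tmean <- (tmax + tmin) / 2
  pmax(0, 0.0023 * (tmean + 17.8) * sqrt(tmax - tmin) * 0.408 * ra)
}
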