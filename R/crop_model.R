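#' Daily growing degree-days
#'
#' \code{max(0, (tmax + tmin)/2 - tbase)}. Vectorised.
#'
#' @param tmax,tmin Daily extreme temperatures, degrees C; tmax >= tmin.
#' @param tbase Base temperature, degrees C.
#' @return Degree C days (>= 0).
#' @export
#' @examples
#' gdd(30, 20, 10) # 15
gdd <- function(tmax, tmin, tbase) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  pmax(0, (tmax + tmin) / 2 - tbase)
}

# Basal crop coefficient for a development fraction (piecewise constant over
# the four stages; fraction = accumulated GDD / requirement).
kcb_at <- function(crop, frac) {
  stage <- findInterval(frac, crop$stage_fractions) + 1L
  crop$kcb_stages[pmin(stage, 4L)]
}

#' Run the crop surrogate over one season
#'
#' A minimal, declared stand-in for a full crop-water model (AquaCrop
#' class): from the planting day it accumulates GDD until the crop's
#' requirement is met (maturity) or the weather series ends, running a
#' daily soil-water bucket of total available water
#' TAW = (fc - wp) * root_depth * 1000 mm. Each day, transpiration is
#' \code{Ks * Kcb(stage) * ET0} with the stress coefficient Ks falling
#' linearly from 1 to 0 as depletion grows from RAW = p * TAW to TAW; soil
#' evaporation is \code{Ke * ET0 * (1 - Kcb/max(Kcb))}; both fluxes are
#' jointly rescaled so the bucket never goes negative, and water above TAW
#' is discarded as drainage/runoff. Biomass accumulates as
#' \code{wp_star * Tr/ET0} (g/m2, skipped when ET0 = 0) and yield is
#' harvest index times biomass. Reference ET is the Hargreaves
#' temperature/radiation form by default; a per-day \code{et0} column on
#' the weather series, if present, overrides it (plug point for other
#' formulations).
#'
#' @param weather A \code{\link{weather_series}} covering the planting day
#'   onward.
#' @param crop A \code{\link{crop_params}}.
#' @param soil A \code{\link{soil_params}}.
#' @param latitude Site latitude; defaults to the series' attribute.
#' @return An object of class \code{season_result}: list with
#'   \code{season_precip, et_sum, transpiration_sum, biomass, yield, lgp,
#'   matured} plus the balance terms \code{w_init, w_end, drainage} (all
#'   water terms in mm, biomass/yield in t/ha).
#' @export
#' @examples
#' cfg <- climate_config()
#' ws <- generate_truth(cfg, 2006, seed = 1)
#' cp <- crop_params("maize", 110, 1450, 10, c(0.3, 0.8, 1.15, 0.7),
#'                   c(0.2, 0.45, 0.8), 0.3, 33, 0.48, 1.0, 0.55)
#' sp <- soil_params(0.33, 0.17, 0.46, 0.8)
#' run_season(ws, cp, sp)
run_season <- function(weather, crop, soil,
                       latitude = attr(weather, "latitude")) {
  crop <- validate_crop_params(crop)
  soil <- validate_soil_params(soil)
  doy <- as.POSIXlt(as.Date(weather$date))$yday + 1L
  idx <- which(doy >= crop$planting_doy)
  if (!length(idx))
    stop("weather series ends before planting day ", crop$planting_doy)
  days <- weather[idx, , drop = FALSE]
  nd <- nrow(days)

  et0 <- if (!is.null(weather$et0)) weather$et0[idx] else {
    if (is.null(latitude))
      stop("latitude needed to compute reference ET (none on series)")
    hargreaves_et0(days$tmax, days$tmin,
                   extraterrestrial_radiation(doy[idx], latitude))
  }
  g <- gdd(days$tmax, days$tmin, crop$tbase)

  taw <- (soil$fc - soil$wp) * crop$root_depth * 1000
  raw <- crop$depletion_p * taw
  kcb_max <- max(crop$kcb_stages)
  w0 <- soil$initial_fill * taw

  w <- w0
  cum_gdd <- 0
  et_sum <- 0; tr_sum <- 0; biomass_gm2 <- 0
  precip_sum <- 0; drainage <- 0
  lgp <- 0; matured <- FALSE

  for (d in seq_len(nd)) {
    lgp <- d
    frac <- cum_gdd / crop$gdd_requirement
    kcb <- kcb_at(crop, frac)

    depletion <- taw - w
    ks <- if (depletion <= raw) 1
          else max(0, (taw - depletion) / (taw - raw))
    tr <- ks * kcb * et0[d]
    ev <- crop$ke_soil * et0[d] * (1 - if (kcb_max > 0) kcb / kcb_max else 0)
    et_day <- tr + ev
    avail <- w + days$precip[d]
    if (et_day > avail) {          # joint cap: bucket never below zero
      scale <- if (et_day > 0) avail / et_day else 0
      tr <- tr * scale
      ev <- ev * scale
      et_day <- tr + ev
    }
    wn <- w + days$precip[d] - et_day
    if (wn > taw) {
      drainage <- drainage + (wn - taw)
      wn <- taw
    }
    w <- wn

    if (et0[d] > 0) biomass_gm2 <- biomass_gm2 + crop$wp_star * tr / et0[d]
    tr_sum <- tr_sum + tr
    et_sum <- et_sum + et_day
    precip_sum <- precip_sum + days$precip[d]

    cum_gdd <- cum_gdd + g[d]
    if (cum_gdd >= crop$gdd_requirement) {
      matured <- TRUE
      break
    }
  }

  biomass <- biomass_gm2 * 0.01 # g/m2 -> t/ha
  structure(list(
    season_precip = precip_sum,
    et_sum = et_sum,
    transpiration_sum = tr_sum,
    biomass = biomass,
    yield = crop$hi * biomass,
    lgp = lgp,
    matured = matured,
    w_init = w0,
    w_end = w,
    drainage = drainage,
    crop = crop$name,
    realization = attr(weather, "realization")
  ), class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf(
    "<season_result> %s [%s]: lgp %d d (%s), precip %.1f mm, ET %.1f mm, yield %.2f t/ha\n",
    x$crop %||% "?", x$realization %||% "?", x$lgp,
    if (x$matured) "matured" else "cut off", x$season_precip, x$et_sum,
    x$yield))
  invisible(x)
}

#' Seasonal water-balance closure of a season result
#'
#' Returns \code{season_precip - et_sum - drainage - (w_end - w_init)},
#' which a conservative simulation closes to numerical precision.
#'
#' @param result A \code{season_result}.
#' @return Closure residual in mm.
#' @export
water_balance_residual <- function(result) {
  result$season_precip - result$et_sum - result$drainage -
    (result$w_end - result$w_init)
}
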