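# 1 mm of water over 1 ha = 10 m3; single named constant so an alternative
# volume convention is a one-line change.
GWF_M3_PER_MM_HA <- 10

#' Green water footprint
#'
#' Volume of green water (evapotranspired soil moisture of rain origin)
#' consumed per tonne of yield:
#' \code{GWF = 10 * sum(ET_d) / Y} in m3/t, with ET summed over the length
#' of the growing period (mm) and yield Y in t/ha.
#'
#' @param et_sum Accumulated crop evapotranspiration over the growing
#'   period, mm (>= 0).
#' @param yield Crop yield, t/ha; must be > 0 — a failed crop has an
#'   undefined footprint and is reported as an error, never silently
#'   dropped.
#' @return Green water footprint, m3/t.
#' @export
#' @examples
#' green_water_footprint(500, 5) # 1000 m3/t
green_water_footprint <- function(et_sum, yield) {
  if (any(et_sum < 0)) stop("et_sum must be >= 0")
  if (any(yield <= 0))
    stop("green water footprint undefined for yield <= 0 (crop failure)")
  GWF_M3_PER_MM_HA * et_sum / yield
}

#' Water productivity for yield
#'
#' Yield produced per unit volume of evapotranspired water:
#' \code{WPet = 100 * Y / sum(ET_d)} in kg/m3 (Y in t/ha, ET in mm). Under
#' these definitions WPet is the exact reciprocal of the green water
#' footprint times 1000 kg/t.
#'
#' @param yield Crop yield, t/ha (>= 0).
#' @param et_sum Accumulated evapotranspiration, mm (> 0).
#' @return Water productivity, kg/m3.
#' @export
#' @examples
#' water_productivity(5, 500) # 1 kg/m3
#' water_productivity(5, 500) * green_water_footprint(500, 5) # 1000
water_productivity <- function(yield, et_sum) {
  if (any(yield < 0)) stop("yield must be >= 0")
  if (any(et_sum <= 0)) stop("et_sum must be > 0")
  100 * yield / et_sum
}

#' Derived water indicators for one season run
#'
#' Collects the five verified variables of one crop-model run: growing
#' season precipitation, accumulated ET, yield, green water footprint and
#' water productivity. GWF/WPet are NA (with a warning) for failed crops
#' (zero yield) or zero-ET seasons.
#'
#' @param result A \code{\link{run_season}} result.
#' @return A one-row data.frame with columns \code{precip, et, yield, gwf,
#'   wpet}.
#' @export
water_indicators <- function(result) {
  gwf <- wpet <- NA_real_
  if (result$yield > 0 && result$et_sum > 0) {
    gwf <- green_water_footprint(result$et_sum, result$yield)
    wpet <- water_productivity(result$yield, result$et_sum)
  } else {
    warning(sprintf(
      "crop failure or zero ET (%s, %s): GWF/WPet undefined",
      result$crop %||% "?", result$realization %||% "?"))
  }
  data.frame(precip = result$season_precip, et = result$et_sum,
             yield = result$yield, gwf = gwf, wpet = wpet)
}
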