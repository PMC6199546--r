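#' Crop parameter set for the water-driven crop surrogate
#'
#' Phenology is driven by growing degree-days (GDD) above \code{tbase} from
#' the planting day; canopy development is represented by four basal crop
#' coefficients (initial, development, mid, late) switching at fixed
#' fractions of the GDD requirement; biomass accumulates as normalized
#' water productivity times the daily transpiration/reference-ET ratio, and
#' yield is harvest index times biomass.
#'
#' @param name Crop name.
#' @param planting_doy Planting day of year.
#' @param gdd_requirement GDD sum to maturity, degree C days (> 0).
#' @param tbase Base temperature for GDD, degrees C.
#' @param kcb_stages Four basal crop coefficients, dimensionless >= 0, in
#'   stage order initial/development/mid/late.
#' @param stage_fractions Three strictly increasing fractions of
#'   \code{gdd_requirement} in (0, 1\] ending stages 1--3 (stage 4 runs to
#'   maturity).
#' @param ke_soil Soil-evaporation coefficient, dimensionless >= 0.
#' @param wp_star Normalized water productivity, g/m2 of biomass per unit
#'   of accumulated Tr/ET0 (> 0).
#' @param hi Harvest index, in (0, 1\].
#' @param root_depth Effective rooting depth, m (> 0).
#' @param depletion_p Fraction of total available water depletable without
#'   transpiration stress, in (0, 1).
#' @return An object of class \code{crop_params}.
#' @export
#' @examples
#' crop_params("maize", 110, 1450, 10, c(0.3, 0.8, 1.15, 0.7),
#'             c(0.2, 0.45, 0.8), 0.3, 33, 0.48, 1.0, 0.55)
crop_params <- function(name, planting_doy, gdd_requirement, tbase,
                        kcb_stages, stage_fractions, ke_soil, wp_star, hi,
                        root_depth, depletion_p) {
  cp <- structure(as.list(environment()), class = "crop_params")
  validate_crop_params(cp)
}

#' Validate crop parameters
#' @param cp A \code{crop_params} object or equivalent list.
#' @return The validated, classed object.
#' @export
validate_crop_params <- function(cp) {
  if (cp$planting_doy < 1 || cp$planting_doy > 366)
    stop("planting_doy must be in 1..366")
  if (cp$gdd_requirement <= 0) stop("gdd_requirement must be > 0")
  if (length(cp$kcb_stages) != 4 || any(cp$kcb_stages < 0))
    stop("kcb_stages must be four coefficients >= 0")
  sf <- cp$stage_fractions
  if (length(sf) != 3 || any(diff(sf) <= 0) || sf[1] <= 0 || sf[3] > 1)
    stop("stage_fractions must be three strictly increasing fractions in (0, 1]")
  if (cp$ke_soil < 0) stop("ke_soil must be >= 0")
  if (cp$wp_star <= 0) stop("wp_star must be > 0")
  if (cp$hi <= 0 || cp$hi > 1) stop("hi must be in (0, 1]")
  if (cp$root_depth <= 0) stop("root_depth must be > 0")
  if (cp$depletion_p <= 0 || cp$depletion_p >= 1)
    stop("depletion_p must be in (0, 1)")
  class(cp) <- "crop_params"
  cp
}

#' Soil hydrological parameter set
#'
#' Volumetric water contents defining the soil water bucket: wilting point
#' < field capacity < saturation. \code{initial_fill} sets the fraction of
#' total available water (TAW) present at planting.
#'
#' @param fc Field capacity, volumetric fraction.
#' @param wp Wilting point, volumetric fraction.
#' @param sat Saturation, volumetric fraction.
#' @param initial_fill Initial fraction of TAW filled, in \[0, 1\].
#' @return An object of class \code{soil_params}.
#' @export
soil_params <- function(fc, wp, sat, initial_fill = 1) {
  sp <- structure(list(fc = fc, wp = wp, sat = sat,
                       initial_fill = initial_fill),
                  class = "soil_params")
  validate_soil_params(sp)
}

#' Validate soil parameters
#' @param sp A \code{soil_params} object or equivalent list.
#' @return The validated, classed object.
#' @export
validate_soil_params <- function(sp) {
  if (!(sp$wp > 0 && sp$wp < sp$fc && sp$fc < sp$sat && sp$sat < 1))
    stop("require 0 < wp < fc < sat < 1")
  if (sp$initial_fill < 0 || sp$initial_fill > 1)
    stop("initial_fill must be in [0, 1]")
  class(sp) <- "soil_params"
  sp
}

#' Read crop parameters from a YAML file
#'
#' One YAML document per crop with field names exactly as in
#' \code{\link{crop_params}}.
#'
#' @param path YAML file path.
#' @return A validated \code{crop_params}.
#' @export
read_crop_params <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(crop_params, doc[names(formals(crop_params))])
}

#' Read soil parameters from a YAML file
#' @param path YAML file path with \code{\link{soil_params}} field names.
#' @return A validated \code{soil_params}.
#' @export
read_soil_params <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$soil)) doc <- doc$soil
  do.call(soil_params, doc[intersect(names(doc), names(formals(soil_params)))])
}

#' @export
print.crop_params <- function(x, ...) {
  cat(sprintf("<crop_params> %s: planting doy %d, GDD %g (tbase %g C), WP* %g g/m2, HI %.2f\n",
              x$name, x$planting_doy, x$gdd_requirement, x$tbase,
              x$wp_star, x$hi))
  invisible(x)
}

#' @export
print.soil_params <- function(x, ...) {
  cat(sprintf("<soil_params> wp %.2f < fc %.2f < sat %.2f; initial fill %.0f%% of TAW\n",
              x$wp, x$fc, x$sat, 100 * x$initial_fill))
  invisible(x)
}
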