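#' Climate configuration for the synthetic weather generator
#'
#' Bundles the statistical parameters of one site's synthetic growing-season
#' climate: a seasonal temperature cycle with autocorrelated day-to-day
#' noise, two-state Markov-chain precipitation occurrence with gamma wet-day
#' amounts, a sunshine-fraction model feeding the Angstrom--Prescott
#' radiation estimate, and the perturbation scheme that turns one "truth"
#' season into a control run plus ensemble members.
#'
#' Defaults emulate a moderate-continental Pannonian-plain growing season
#' (mean annual temperature ~11.5 degrees C, ~630 mm annual precipitation).
#'
#' @param latitude Site latitude, decimal degrees, strictly inside (-66, 66).
#' @param temp_mean Annual-mean daily mean temperature, degrees C.
#' @param temp_amplitude Amplitude of the annual temperature cycle, degrees C.
#' @param temp_phase_doy Day of year of the warmest day.
#' @param temp_noise_sd Standard deviation of day-to-day temperature noise,
#'   degrees C.
#' @param temp_autocorr Lag-1 autocorrelation of the temperature noise,
#'   in \[0, 1).
#' @param diurnal_range Fixed tmax - tmin diurnal range, degrees C (> 0).
#' @param p01 Probability of a wet day following a dry day, in \[0, 1\].
#' @param p11 Probability of a wet day following a wet day, in \[0, 1\].
#' @param gamma_shape,gamma_scale Gamma law of wet-day precipitation amounts
#'   (shape dimensionless, scale mm); both > 0.
#' @param sunshine_mean Mean relative sunshine fraction on dry days, \[0, 1\].
#' @param sunshine_sd Standard deviation of the sunshine fraction.
#' @param wet_day_sunshine_factor Multiplier applied to the sunshine
#'   fraction on wet days, \[0, 1\].
#' @param prescott_a,prescott_b Angstrom--Prescott coefficients.
#' @param rhum_mean,rhum_sd Relative-humidity noise model, percent
#'   (clipped to \[0, 100\]).
#' @param wind_mean,wind_sd Wind-speed noise model, m/s (clipped at 0).
#' @param member_temp_bias Additive temperature bias of the forecast system,
#'   degrees C (applied to control and members).
#' @param member_precip_bias Multiplicative precipitation bias (> 0,
#'   applied to control and members).
#' @param member_inflation Ensemble noise inflation (>= 0). Scales the
#'   member temperature noise, the member wet-day amount noise and the
#'   occurrence decoupling; 0 makes every member identical to the biased
#'   control.
#' @param member_temp_sd Base member temperature noise sd at inflation 1,
#'   degrees C.
#' @param member_precip_sdlog Base sdlog of the mean-one lognormal member
#'   wet-day amount perturbation at inflation 1.
#' @param member_occurrence_decoupling Base probability (at inflation 1)
#'   that a member day's wet/dry state is re-drawn from its own Markov chain
#'   instead of copied from truth; effective weight is
#'   \code{min(1, inflation * decoupling)}.
#' @param members_per_year Named list or vector mapping calendar year to
#'   ensemble size N (>= 2). Years absent from the map fall back to
#'   \code{default_members}.
#' @param default_members Ensemble size used for unmapped years.
#' @return An object of class \code{climate_config}.
#' @export
#' @examples
#' cfg <- climate_config(latitude = 45.3)
#' cfg$p01
climate_config <- function(latitude = 45.3,
                           temp_mean = 11.5,
                           temp_amplitude = 11,
                           temp_phase_doy = 200,
                           temp_noise_sd = 2,
                           temp_autocorr = 0.6,
                           diurnal_range = 10,
                           p01 = 0.25,
                           p11 = 0.55,
                           gamma_shape = 0.8,
                           gamma_scale = 6,
                           sunshine_mean = 0.6,
                           sunshine_sd = 0.15,
                           wet_day_sunshine_factor = 0.5,
                           prescott_a = 0.25,
                           prescott_b = 0.50,
                           rhum_mean = 70,
                           rhum_sd = 8,
                           wind_mean = 2,
                           wind_sd = 0.8,
                           member_temp_bias = 0,
                           member_precip_bias = 1,
                           member_inflation = 1,
                           member_temp_sd = 1,
                           member_precip_sdlog = 0.3,
                           member_occurrence_decoupling = 0.5,
                           members_per_year = NULL,
                           default_members = 10) {
  cfg <- structure(as.list(environment()), class = "climate_config")
  validate_climate_config(cfg)
}

#' Validate a climate configuration
#'
#' @param cfg A \code{climate_config} object (or plain list with the same
#'   fields, e.g. parsed from YAML).
#' @return The validated object, invisibly classed as
#'   \code{climate_config}.
#' @export
validate_climate_config <- function(cfg) {
  with(cfg, {
    if (latitude <= -66 || latitude >= 66)
      stop("latitude must lie strictly between -66 and 66")
    if (temp_autocorr < 0 || temp_autocorr >= 1)
      stop("temp_autocorr must be in [0, 1)")
    if (temp_noise_sd < 0) stop("temp_noise_sd must be >= 0")
    if (diurnal_range <= 0) stop("diurnal_range must be > 0")
    for (p in c(p01, p11)) if (p < 0 || p > 1)
      stop("transition probabilities must be in [0, 1]")
    if (gamma_shape <= 0 || gamma_scale <= 0)
      stop("gamma shape and scale must be positive")
    if (sunshine_mean < 0 || sunshine_mean > 1)
      stop("sunshine_mean must be in [0, 1]")
    if (wet_day_sunshine_factor < 0 || wet_day_sunshine_factor > 1)
      stop("wet_day_sunshine_factor must be in [0, 1]")
    if (member_precip_bias <= 0) stop("member_precip_bias must be > 0")
    if (member_inflation < 0) stop("member_inflation must be >= 0")
  })
  ns <- unlist(cfg$members_per_year)
  if (length(ns) && any(ns < 2)) stop("every ensemble size must be >= 2")
  if (cfg$default_members < 2) stop("default_members must be >= 2")
  class(cfg) <- "climate_config"
  cfg
}

#' Ensemble size for a given year
#'
#' Looks the year up in the config's \code{members_per_year} map, falling
#' back to \code{default_members}. The default map mirrors an operational
#' seasonal system growing from 10 members in 2006 to 50 in 2014.
#'
#' @param cfg A \code{climate_config}.
#' @param year Calendar year.
#' @return Integer ensemble size N >= 2.
#' @export
members_for_year <- function(cfg, year) {
  m <- cfg$members_per_year
  if (!is.null(m)) {
    v <- m[[as.character(year)]]
    if (!is.null(v)) return(as.integer(v))
  }
  as.integer(cfg$default_members)
}

#' Default member ramp, 10 members in 2006 rising to 50 in 2014
#'
#' A stylised linear ramp of ensemble size over the nine seasons 2006--2014.
#'
#' @return Named list year -> N suitable for
#'   \code{climate_config(members_per_year = ...)}.
#' @export
default_member_ramp <- function() {
  yrs <- 2006:2014
  stats::setNames(as.list(as.integer(round(seq(10, 50, length.out = 9)))),
                  as.character(yrs))
}

#' @export
print.climate_config <- function(x, ...) {
  cat(sprintf(
    "<climate_config> lat %.2f; T %.1f +/- %.1f C (peak doy %d); p01 %.2f p11 %.2f; gamma(%.2f, %.1f mm)\n",
    x$latitude, x$temp_mean, x$temp_amplitude, x$temp_phase_doy,
    x$p01, x$p11, x$gamma_shape, x$gamma_scale))
  cat(sprintf(
    "  ensemble: temp bias %+.2f C, precip bias x%.2f, inflation %.2f\n",
    x$member_temp_bias, x$member_precip_bias, x$member_inflation))
  invisible(x)
}

#' Read a climate configuration from YAML
#'
#' Expects a top-level \code{climate:} block (or a bare mapping) whose keys
#' mirror the \code{\link{climate_config}} arguments.
#'
#' @param path Path to a YAML file.
#' @return A validated \code{climate_config}.
#' @export
read_climate_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$climate)) doc <- doc$climate
  known <- names(formals(climate_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown climate config fields: ", paste(unknown, collapse = ", "))
  do.call(climate_config, doc)
}
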