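#' Generate one synthetic observed ("truth") season
#'
#' Produces a complete 1 March -- 1 October daily series for one year:
#' mean temperature follows the configured annual cycle plus AR(1) noise
#' (innovation variance scaled so the stationary sd equals
#' \code{temp_noise_sd}), a fixed diurnal range splits it into tmax/tmin,
#' precipitation occurrence follows the two-state Markov chain (initialised
#' at its stationary wet-day frequency) with gamma wet-day amounts, and
#' global radiation is derived from a sampled sunshine fraction through the
#' Angstrom--Prescott relation. Identical (config, year, seed) reproduce an
#' identical series; the caller's RNG state is left untouched.
#'
#' @param config A \code{\link{climate_config}}.
#' @param year Calendar year of the season.
#' @param seed Integer seed for this realization.
#' @param site_id Site identifier attached to the series.
#' @return A \code{\link{weather_series}} with realization \code{"OB"}.
#' @export
#' @examples
#' truth <- generate_truth(climate_config(), 2006, seed = 1)
#' sum(truth$precip)
generate_truth <- function(config, year, seed, site_id = "site") {
  config <- validate_climate_config(config)
  dates <- season_dates(year)
  doy <- as.POSIXlt(dates)$yday + 1L
  n <- length(dates)
  with_seed(seed, {
    rho <- config$temp_autocorr
    innov <- stats::rnorm(n, 0, config$temp_noise_sd * sqrt(1 - rho^2))
    eps <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    tmean <- config$temp_mean +
      config$temp_amplitude * cos(2 * pi * (doy - config$temp_phase_doy) / 365.25) +
      eps
    tmax <- tmean + config$diurnal_range / 2
    tmin <- tmean - config$diurnal_range / 2

    wet <- markov_occurrence(n, config$p01, config$p11)
    precip <- numeric(n)
    nwet <- sum(wet)
    if (nwet > 0)
      precip[wet] <- stats::rgamma(nwet, shape = config$gamma_shape,
                                   scale = config$gamma_scale)

    frac <- stats::rnorm(n, config$sunshine_mean, config$sunshine_sd)
    frac[wet] <- frac[wet] * config$wet_day_sunshine_factor
    frac <- clip(frac, 0, 1)
    ra <- extraterrestrial_radiation(doy, config$latitude)
    srad <- prescott_radiation(frac, ra, config$prescott_a, config$prescott_b)

    rhum <- clip(stats::rnorm(n, config$rhum_mean, config$rhum_sd), 0, 100)
    wind <- pmax(0, stats::rnorm(n, config$wind_mean, config$wind_sd))

    weather_series(
      data.frame(date = dates, tmax = tmax, tmin = tmin, rhum = rhum,
                 wind = wind, srad = srad, precip = precip),
      site_id = site_id, realization = "OB", latitude = config$latitude)
  })
}

# Two-state Markov wet/dry chain started from its stationary wet frequency
# p01 / (1 + p01 - p11).
markov_occurrence <- function(n, p01, p11) {
  wet <- logical(n)
  pstat <- stationary_wet_frequency(p01, p11)
  u <- stats::runif(n)
  wet[1] <- u[1] < pstat
  for (t in seq_len(n)[-1])
    wet[t] <- u[t] < if (wet[t - 1]) p11 else p01
  wet
}

#' Stationary wet-day frequency of the occurrence chain
#'
#' @param p01 Dry-to-wet transition probability.
#' @param p11 Wet-to-wet transition probability.
#' @return p01 / (1 + p01 - p11).
#' @export
stationary_wet_frequency <- function(p01, p11) p01 / (1 + p01 - p11)

#' Perturb a truth season into a control run and ensemble members
#'
#' Emulates a seasonal ensemble prediction system around a known truth. The
#' control run applies only the configured systematic biases (additive
#' temperature, multiplicative precipitation); each ensemble member
#' additionally receives independent noise: an additive temperature
#' perturbation (the same draw on tmax and tmin, preserving the diurnal
#' range), a mean-one lognormal factor on wet-day precipitation amounts,
#' and partially re-drawn precipitation occurrence. Occurrence decoupling
#' works day-by-day: with probability \code{min(1, inflation * decoupling)}
#' a member's wet/dry state is drawn from its own Markov chain (conditioned
#' on the member's previous day), otherwise it copies the truth; this keeps
#' realistic wet/dry spell statistics at every decoupling level. With
#' inflation 0 every member equals the biased control exactly.
#'
#' Members are drawn jointly (vectorised across the ensemble) from a single
#' stream seeded by \code{seed}: the output is fully determined by
#' (truth, n_members, config, seed).
#'
#' @param truth A \code{\link{weather_series}} (realization "OB").
#' @param n_members Ensemble size N >= 2.
#' @param config A \code{\link{climate_config}}.
#' @param seed Integer seed for the ensemble stream.
#' @return List with elements \code{control} (a \code{weather_series},
#'   realization "CR") and \code{members} (list of N series, realizations
#'   "M01"...).
#' @export
perturb_members <- function(truth, n_members, config, seed) {
  config <- validate_climate_config(config)
  if (n_members < 2) stop("n_members must be >= 2")
  n <- nrow(truth)
  site <- attr(truth, "site_id")
  lat <- attr(truth, "latitude")

  bias_t <- config$member_temp_bias
  bias_p <- config$member_precip_bias

  control <- weather_series(
    data.frame(date = truth$date,
               tmax = truth$tmax + bias_t, tmin = truth$tmin + bias_t,
               rhum = truth$rhum, wind = truth$wind, srad = truth$srad,
               precip = truth$precip * bias_p),
    site_id = site, realization = "CR", latitude = lat)

  infl <- config$member_inflation
  tsd <- infl * config$member_temp_sd
  sdlog <- infl * config$member_precip_sdlog
  w <- min(1, infl * config$member_occurrence_decoupling)
  truth_wet <- truth$precip > 0
  pstat <- stationary_wet_frequency(config$p01, config$p11)

  members <- with_seed(seed, {
    tnoise <- matrix(stats::rnorm(n * n_members, 0, tsd), n, n_members)

    # occurrence: day loop, vectorised across members
    wet_m <- matrix(FALSE, n, n_members)
    if (w > 0) {
      for (t in seq_len(n)) {
        own <- stats::runif(n_members) < w
        p_chain <- if (t == 1) rep(pstat, n_members) else {
          p <- rep(config$p01, n_members)
          p[wet_m[t - 1, ]] <- config$p11
          p
        }
        draw <- stats::runif(n_members) < p_chain
        row <- rep(truth_wet[t], n_members)
        row[own] <- draw[own]
        wet_m[t, ] <- row
      }
    } else {
      wet_m[] <- truth_wet
    }

    # amounts: perturb truth's amount where truth is wet, fresh gamma draw
    # where only the member is wet; lognormal factor has mean exactly 1
    lnfac <- matrix(stats::rlnorm(n * n_members, -sdlog^2 / 2, sdlog),
                    n, n_members)
    amt <- matrix(stats::rgamma(n * n_members, shape = config$gamma_shape,
                                scale = config$gamma_scale), n, n_members)
    if (any(truth_wet))
      amt[truth_wet, ] <- truth$precip[truth_wet] *
        lnfac[truth_wet, , drop = FALSE]
    amt <- amt * bias_p
    amt[!wet_m] <- 0

    lapply(seq_len(n_members), function(k) {
      # members satisfy the series invariants by construction (shared
      # tmax/tmin perturbation preserves the diurnal range; amounts >= 0),
      # so the fast unvalidated constructor is safe here
      new_weather_series(
        date = truth$date,
        tmax = truth$tmax + bias_t + tnoise[, k],
        tmin = truth$tmin + bias_t + tnoise[, k],
        rhum = truth$rhum, wind = truth$wind, srad = truth$srad,
        precip = amt[, k],
        site_id = site, realization = sprintf("M%02d", k), latitude = lat)
    })
  })

  list(control = control, members = members)
}
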