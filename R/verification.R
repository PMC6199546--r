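#' One year's ensemble outcome for a (site, crop, variable)
#'
#' Holds the ensemble member values Y_i, the control-run value Y^CR and the
#' observation-based value Y^OB of one verified variable, plus the derived
#' ensemble average Y^EA.
#'
#' @param year Calendar year.
#' @param site Site identifier.
#' @param crop Crop name.
#' @param variable One of \code{"precip", "et", "yield", "gwf", "wpet"}.
#' @param members Numeric vector of >= 2 finite member values.
#' @param control Control-run value (may be NA when no control exists).
#' @param observed Observation-based value.
#' @return An object of class \code{ensemble_outcome}.
#' @export
#' @examples
#' o <- ensemble_outcome(2006, "ns", "maize", "yield", c(1, 2, 3), 2.1, 2)
#' o$ensemble_average
ensemble_outcome <- function(year, site, crop, variable, members,
                             control = NA_real_, observed) {
  if (length(members) < 2) stop("need at least 2 ensemble members")
  if (!all(is.finite(members))) stop("member values must be finite")
  if (!is.finite(observed)) stop("observed value must be finite")
  structure(list(year = year, site = site, crop = crop,
                 variable = variable, members = as.numeric(members),
                 control = control, observed = observed,
                 ensemble_average = mean(members)),
            class = "ensemble_outcome")
}

#' @export
print.ensemble_outcome <- function(x, ...) {
  cat(sprintf(
    "<ensemble_outcome> %d %s/%s %s: N=%d, EA=%.4g, CR=%.4g, OB=%.4g\n",
    x$year, x$site, x$crop, x$variable, length(x$members),
    x$ensemble_average, x$control, x$observed))
  invisible(x)
}

#' Per-year ensemble RMSE against the observation-based value
#'
#' Forecast accuracy of the ensemble in one year:
#' \code{sqrt(mean((Y_i - Y_OB)^2))} over the N members (population, 1/N
#' divisor by default, so that \code{rmse^2 = sprd^2 + (Y_EA - Y_OB)^2}
#' holds exactly; a 1/(N-1) variant is available).
#'
#' @param outcome An \code{\link{ensemble_outcome}}.
#' @param convention \code{"population"} (1/N, default) or \code{"sample"}
#'   (1/(N-1)).
#' @return RMSE in the variable's units.
#' @export
#' @examples
#' year_rmse(ensemble_outcome(2006, "s", "c", "yield", c(1, 2, 3),
#'                            observed = 2)) # sqrt(2/3)
year_rmse <- function(outcome, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  y <- outcome$members
  n <- length(y)
  ss <- sum((y - outcome$observed)^2)
  sqrt(ss / if (convention == "population") n else n - 1)
}

#' Per-year ensemble spread
#'
#' Dispersion of the members around their own mean:
#' \code{sqrt(mean((Y_i - Y_EA)^2))}. An ideal ensemble forecast has equal
#' RMSE and spread.
#'
#' @inheritParams year_rmse
#' @return Spread in the variable's units.
#' @export
#' @examples
#' year_spread(ensemble_outcome(2006, "s", "c", "yield", c(2, 4, 6),
#'                              observed = 4)) # sqrt(8/3)
year_spread <- function(outcome, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  y <- outcome$members
  n <- length(y)
  ss <- sum((y - outcome$ensemble_average)^2)
  sqrt(ss / if (convention == "population") n else n - 1)
}

#' Pielke realism criteria
#'
#' Criterion (a): the simulation RMSE is below the standard deviation of
#' the observed values. Criterion (b): the simulated standard deviation is
#' close to the observed one; "close" is made explicit as a ratio band
#' \code{[1/closeness_band, closeness_band]}.
#'
#' @param rmse_sim RMSE of the simulated dataset against observations.
#' @param sigma_sim Standard deviation of the simulated dataset.
#' @param sigma_obs Standard deviation of the observed dataset (> 0).
#' @param closeness_band Ratio band half-width for criterion (b); >= 1,
#'   default 2.
#' @return List \code{(skill_a, skill_b)} of logicals.
#' @export
#' @examples
#' pielke_skill(0.5, 0.9, 1.0) # both TRUE
pielke_skill <- function(rmse_sim, sigma_sim, sigma_obs,
                         closeness_band = 2) {
  if (sigma_obs <= 0) stop("sigma_obs must be > 0")
  if (closeness_band < 1) stop("closeness_band must be >= 1")
  ratio <- sigma_sim / sigma_obs
  list(skill_a = rmse_sim < sigma_obs,
       skill_b = ratio >= 1 / closeness_band & ratio <= closeness_band)
}

#' Per-year verification statistics
#'
#' RMSE, spread and ensemble-average error for one outcome; when the
#' multi-year observed standard deviation is supplied, the Pielke criteria
#' are evaluated with the year's RMSE (a) and spread (b).
#'
#' @inheritParams year_rmse
#' @param sigma_obs Multi-year standard deviation of the observed values
#'   (optional).
#' @param closeness_band Passed to \code{\link{pielke_skill}}.
#' @return List with \code{rmse, sprd, ea_error, skill_a, skill_b}.
#' @export
year_stats <- function(outcome, sigma_obs = NULL, closeness_band = 2,
                       convention = c("population", "sample")) {
  convention <- match.arg(convention)
  rmse <- year_rmse(outcome, convention)
  sprd <- year_spread(outcome, convention)
  ea_error <- outcome$ensemble_average - outcome$observed
  skill_a <- skill_b <- NA
  if (!is.null(sigma_obs) && is.finite(sigma_obs) && sigma_obs > 0) {
    sk <- pielke_skill(rmse, sprd, sigma_obs, closeness_band)
    skill_a <- sk$skill_a
    skill_b <- sk$skill_b
  }
  list(rmse = rmse, sprd = sprd, ea_error = ea_error,
       skill_a = skill_a, skill_b = skill_b)
}

#' Multi-year summary over the OB, CR and EA datasets
#'
#' For a sequence of yearly outcomes of one (site, crop, variable):
#' per-dataset mean, standard deviation (sample convention, N-1, as the
#' years are a sample) and coefficient of variation for the
#' observation-based (OB), control (CR) and ensemble-average (EA) series,
#' plus the cross-year RMSE of CR and EA against OB and the Pielke skill
#' of each.
#'
#' @param outcomes List of \code{\link{ensemble_outcome}}s for >= 2
#'   distinct years (one per year).
#' @param closeness_band Passed to \code{\link{pielke_skill}}.
#' @return An object of class \code{multi_year_summary}: list with
#'   \code{n_years}, per-dataset \code{mean, sd, cv} (named vectors over
#'   OB/CR/EA), \code{rmse_cr, rmse_ea}, and \code{skill} (list of Pielke
#'   results for CR and EA).
#' @export
multi_year_summary <- function(outcomes, closeness_band = 2) {
  if (length(outcomes) < 2) stop("need outcomes for at least 2 years")
  ob <- vapply(outcomes, function(o) o$observed, numeric(1))
  cr <- vapply(outcomes, function(o) as.numeric(o$control), numeric(1))
  ea <- vapply(outcomes, function(o) o$ensemble_average, numeric(1))
  series <- list(OB = ob, CR = cr, EA = ea)

  mean_v <- vapply(series, function(x) mean(x, na.rm = TRUE), numeric(1))
  sd_v <- vapply(series, function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  cv_v <- ifelse(mean_v != 0, sd_v / mean_v, NA_real_)

  cross_rmse <- function(x) sqrt(mean((x - ob)^2, na.rm = TRUE))
  rmse_cr <- cross_rmse(cr)
  rmse_ea <- cross_rmse(ea)

  skill <- list(CR = list(skill_a = NA, skill_b = NA),
                EA = list(skill_a = NA, skill_b = NA))
  if (is.finite(sd_v[["OB"]]) && sd_v[["OB"]] > 0) {
    if (is.finite(rmse_cr) && is.finite(sd_v[["CR"]]))
      skill$CR <- pielke_skill(rmse_cr, sd_v[["CR"]], sd_v[["OB"]],
                               closeness_band)
    skill$EA <- pielke_skill(rmse_ea, sd_v[["EA"]], sd_v[["OB"]],
                             closeness_band)
  }

  structure(list(n_years = length(outcomes), mean = mean_v, sd = sd_v,
                 cv = cv_v, rmse_cr = rmse_cr, rmse_ea = rmse_ea,
                 skill = skill, sd_convention = "sample"),
            class = "multi_year_summary")
}

#' @export
print.multi_year_summary <- function(x, ...) {
  cat(sprintf("<multi_year_summary> %d years (sd: sample convention)\n",
              x$n_years))
  for (ds in c("OB", "CR", "EA"))
    cat(sprintf("  %s: mean %.4g, sd %.4g, cv %.3g\n", ds,
                x$mean[[ds]], x$sd[[ds]], x$cv[[ds]]))
  cat(sprintf("  RMSE vs OB: CR %.4g, EA %.4g\n", x$rmse_cr, x$rmse_ea))
  invisible(x)
}
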