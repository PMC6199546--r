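# Shared fixtures: small configs, toy weather builders and simulation
# helpers used across the test files.

test_climate <- function(...) climate_config(...)

test_crop <- function(...) {
  args <- utils::modifyList(list(
    name = "maize", planting_doy = 110, gdd_requirement = 1450, tbase = 10,
    kcb_stages = c(0.3, 0.8, 1.15, 0.7), stage_fractions = c(0.2, 0.45, 0.8),
    ke_soil = 0.3, wp_star = 33, hi = 0.48, root_depth = 1.0,
    depletion_p = 0.55), list(...))
  do.call(crop_params, args)
}

test_soil <- function(...) {
  args <- utils::modifyList(
    list(fc = 0.33, wp = 0.17, sat = 0.46, initial_fill = 0.8), list(...))
  do.call(soil_params, args)
}

# A hand-controllable toy season: constant temperatures, optional fixed
# daily et0 override and precipitation vector.
toy_weather <- function(n_days, tmax = 25, tmin = 15, precip = 0,
                        et0 = NULL, start = "2006-05-01") {
  dates <- seq(as.Date(start), by = "day", length.out = n_days)
  df <- data.frame(date = dates,
                   tmax = rep_len(tmax, n_days),
                   tmin = rep_len(tmin, n_days),
                   rhum = 70, wind = 2, srad = 20,
                   precip = rep_len(precip, n_days))
  ws <- weather_series(df, site_id = "toy", realization = "OB",
                       latitude = 45)
  if (!is.null(et0)) ws$et0 <- rep_len(et0, n_days)
  ws
}

# Member season-total precipitation of a generated ensemble year.
member_precip_totals <- function(ens) {
  vapply(ens$members, function(m) sum(m$precip), numeric(1))
}

# Simulate ignorance scores for synthetic ensemble years: truth + members
# from the weather generator, Gaussian fit on member season precipitation,
# observation drawn from the fitted predictive density shifted by
# `bias_sigma` fitted standard deviations.
simulate_scores <- function(n_years, n_members, config, seed,
                            bias_sigma = 0) {
  scores <- numeric(n_years)
  for (i in seq_len(n_years)) {
    truth <- generate_truth(config, 2000, seed = derive_seed(seed, i, "t"))
    ens <- perturb_members(truth, n_members, config,
                           seed = derive_seed(seed, i, "e"))
    fit <- fit_gaussian(member_precip_totals(ens))
    y <- with_seed_local(derive_seed(seed, i, "o"),
                         stats::rnorm(1, fit$mu + bias_sigma * fit$sigma,
                                      fit$sigma))
    scores[i] <- ignorance_score(y, fit)$score_bits
  }
  scores
}

# local seeded evaluation without touching the suite's RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
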