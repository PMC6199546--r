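#' Experiment configuration
#'
#' Describes a full forecast-verification experiment: one or more sites
#' (each a climate configuration plus soil), one or more crops, an
#' inclusive range of seasons, the master seed and the statistical options
#' threaded through verification and scoring.
#'
#' @param sites List of sites, each a list with \code{name} (character),
#'   \code{climate} (a \code{\link{climate_config}}) and \code{soil}
#'   (a \code{\link{soil_params}}).
#' @param crops List of \code{\link{crop_params}}.
#' @param years Integer vector of >= 2 seasons (default 2006--2014, the
#'   nine-season frame).
#' @param seed Master integer seed; per-(site, year, stage) sub-streams are
#'   derived from it with \code{\link{derive_seed}}.
#' @param sd_convention Ensemble sigma convention for RMSE/spread/fits.
#' @param alpha Normality-screen significance level.
#' @param closeness_band Pielke criterion (b) ratio band.
#' @param high_score_threshold,high_sigma_threshold Ignorance summary
#'   interpretation thresholds, bits.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(sites, crops, years = 2006:2014, seed = 1L,
                              sd_convention = "population",
                              alpha = 0.05, closeness_band = 2,
                              high_score_threshold = 4.21,
                              high_sigma_threshold = 2.0) {
  stopifnot(length(sites) >= 1, length(crops) >= 1, length(years) >= 2)
  for (s in sites) {
    stopifnot(!is.null(s$name))
    validate_climate_config(s$climate)
    validate_soil_params(s$soil)
  }
  for (cp in crops) validate_crop_params(cp)
  structure(list(sites = sites, crops = crops, years = as.integer(years),
                 seed = as.integer(seed), sd_convention = sd_convention,
                 alpha = alpha, closeness_band = closeness_band,
                 high_score_threshold = high_score_threshold,
                 high_sigma_threshold = high_sigma_threshold),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Layout: top-level \code{seed}, \code{years} (list or \code{from}/
#' \code{to}), optional option fields as in
#' \code{\link{experiment_config}}, a \code{sites:} list (each with
#' \code{name}, an inline \code{climate:} block and a \code{soil:} path or
#' inline block) and a \code{crops:} list of YAML paths or inline blocks.
#' Relative paths resolve against the config file's directory.
#'
#' @param path Config YAML path.
#' @param seed Optional seed overriding the file's.
#' @return An \code{\link{experiment_config}}.
#' @export
read_experiment_config <- function(path, seed = NULL) {
  doc <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)

  years <- if (!is.null(doc$years$from))
    seq(doc$years$from, doc$years$to) else unlist(doc$years)

  sites <- lapply(doc$sites, function(s) {
    climate <- if (is.character(s$climate)) read_climate_config(resolve(s$climate))
               else do.call(climate_config, s$climate)
    soil <- if (is.character(s$soil)) read_soil_params(resolve(s$soil))
            else do.call(soil_params, s$soil)
    list(name = s$name, climate = climate, soil = soil)
  })
  crops <- lapply(doc$crops, function(cc) {
    if (is.character(cc)) read_crop_params(resolve(cc))
    else do.call(crop_params, cc[names(formals(crop_params))])
  })
  opts <- doc[intersect(names(doc),
                        c("sd_convention", "alpha", "closeness_band",
                          "high_score_threshold", "high_sigma_threshold"))]
  do.call(experiment_config,
          c(list(sites = sites, crops = crops, years = years,
                 seed = seed %||% doc$seed %||% 1L), opts))
}

#' Run the full forecast-verification experiment
#'
#' For every (site, year): generates the synthetic truth season and
#' perturbs it into a control run and the year's ensemble; for every crop
#' and realization runs the crop surrogate and derives the five verified
#' variables (growing-season precipitation, ET, yield, green water
#' footprint, water productivity); then verifies the resulting outcome
#' table (RMSE/spread/skill and Ignorance reports). Fully deterministic
#' under a fixed master seed.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param out_dir Optional output directory; when given, all tables are
#'   written as CSV (\code{outcomes.csv}, \code{verification.csv},
#'   \code{verification_summary.csv}, \code{ignorance.csv},
#'   \code{ignorance_summary.csv}) plus a \code{manifest.yaml}.
#' @return A run manifest (class \code{run_manifest}): list with the
#'   \code{outcomes}, \code{verification}, \code{summary},
#'   \code{ignorance}, \code{ignorance_summary} data.frames, the seed,
#'   a config hash, record counts, collected warnings and (if written)
#'   file paths.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  warnings_log <- character()
  rows <- vector("list", 0L)

  for (site in config$sites) {
    for (year in config$years) {
      n_mem <- members_for_year(site$climate, year)
      truth <- generate_truth(site$climate, year,
                              seed = derive_seed(config$seed, site$name,
                                                 year, "truth"),
                              site_id = site$name)
      ens <- perturb_members(truth, n_mem, site$climate,
                             seed = derive_seed(config$seed, site$name,
                                                year, "ensemble"))
      realizations <- c(list(OB = truth, CR = ens$control),
                        stats::setNames(ens$members,
                                        vapply(ens$members,
                                               attr, "", "realization")))
      for (crop in config$crops) {
        for (rname in names(realizations)) {
          res <- withCallingHandlers(
            run_season(realizations[[rname]], crop, site$soil),
            warning = function(w) {
              warnings_log <<- c(warnings_log, conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          ind <- withCallingHandlers(
            water_indicators(res),
            warning = function(w) {
              warnings_log <<- c(warnings_log, sprintf(
                "site %s year %d: %s", site$name, year,
                conditionMessage(w)))
              invokeRestart("muffleWarning")
            })
          rows[[length(rows) + 1L]] <- data.frame(
            year = year, site = site$name, crop = crop$name,
            realization = rname,
            variable = c("precip", "et", "yield", "gwf", "wpet"),
            value = as.numeric(ind[1, c("precip", "et", "yield",
                                        "gwf", "wpet")]))
        }
      }
    }
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL

  rep <- verify_outcome_table(outcomes,
                              sd_convention = config$sd_convention,
                              alpha = config$alpha,
                              closeness_band = config$closeness_band,
                              high_score_threshold = config$high_score_threshold,
                              high_sigma_threshold = config$high_sigma_threshold)
  warnings_log <- c(warnings_log, rep$warnings)

  manifest <- structure(list(
    seed = config$seed,
    config_hash = derive_seed(0L, yaml::as.yaml(unclass(config)[
      c("years", "seed", "sd_convention", "alpha", "closeness_band")])),
    counts = c(outcome_rows = nrow(outcomes),
               verification_rows = nrow(rep$verification),
               ignorance_rows = nrow(rep$ignorance)),
    warnings = warnings_log,
    outcomes = outcomes,
    verification = rep$verification,
    summary = rep$summary,
    ignorance = rep$ignorance,
    ignorance_summary = rep$ignorance_summary,
    paths = NULL
  ), class = "run_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(outcomes = file.path(out_dir, "outcomes.csv"),
               verification = file.path(out_dir, "verification.csv"),
               summary = file.path(out_dir, "verification_summary.csv"),
               ignorance = file.path(out_dir, "ignorance.csv"),
               ignorance_summary = file.path(out_dir,
                                             "ignorance_summary.csv"))
    for (nm in names(paths))
      utils::write.csv(manifest[[nm]], paths[[nm]], row.names = FALSE,
                       quote = FALSE)
    yaml::write_yaml(list(seed = manifest$seed,
                          config_hash = manifest$config_hash,
                          counts = as.list(manifest$counts),
                          warnings = as.list(warnings_log),
                          files = as.list(paths)),
                     file.path(out_dir, "manifest.yaml"))
    manifest$paths <- c(paths, manifest = file.path(out_dir,
                                                    "manifest.yaml"))
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d outcome rows, %d verification rows, %d warnings\n",
              x$seed, x$counts[["outcome_rows"]],
              x$counts[["verification_rows"]], length(x$warnings)))
  invisible(x)
}

# Core verification of a long outcome table (internal; exported wrapper
# verify_from_table handles file IO).
verify_outcome_table <- function(outcomes, sd_convention = "population",
                                 alpha = 0.05, closeness_band = 2,
                                 high_score_threshold = 4.21,
                                 high_sigma_threshold = 2.0) {
  need <- c("year", "site", "crop", "realization", "variable", "value")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("outcome table lacks columns: ",
                         paste(miss, collapse = ", "))
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  ver_rows <- list(); sum_rows <- list()
  ign_rows <- list(); ign_sum_rows <- list()

  groups <- unique(outcomes[c("site", "crop", "variable")])
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    sub <- outcomes[outcomes$site == g$site & outcomes$crop == g$crop &
                    outcomes$variable == g$variable, ]
    gl <- sprintf("%s/%s/%s", g$site, g$crop, g$variable)

    year_outcomes <- list()
    for (year in sort(unique(sub$year))) {
      ys <- sub[sub$year == year, ]
      ob <- ys$value[ys$realization == "OB"]
      cr <- ys$value[ys$realization == "CR"]
      mem <- ys$value[grepl("^M[0-9]+$", ys$realization)]
      dropped <- sum(is.na(mem))
      mem <- mem[is.na(mem) == FALSE]
      if (dropped > 0)
        note("%s year %d: dropped %d member(s) with undefined value",
             gl, year, dropped)
      if (length(ob) != 1 || is.na(ob)) {
        note("%s year %d: missing OB value, year skipped", gl, year)
        next
      }
      if (length(mem) < 2) {
        note("%s year %d: fewer than 2 members, year skipped", gl, year)
        next
      }
      year_outcomes[[as.character(year)]] <-
        ensemble_outcome(year, g$site, g$crop, g$variable, mem,
                         control = if (length(cr) == 1) cr else NA_real_,
                         observed = ob)
    }
    if (!length(year_outcomes)) {
      note("%s: no verifiable years", gl)
      next
    }

    obs <- vapply(year_outcomes, function(o) o$observed, numeric(1))
    sigma_obs <- if (length(obs) >= 2) stats::sd(obs) else NA_real_

    scores <- list()
    for (o in year_outcomes) {
      st <- year_stats(o, sigma_obs = sigma_obs,
                       closeness_band = closeness_band,
                       convention = sd_convention)
      ver_rows[[length(ver_rows) + 1L]] <- data.frame(
        year = o$year, site = o$site, crop = o$crop,
        variable = o$variable, n_members = length(o$members),
        rmse = st$rmse, sprd = st$sprd, ea_error = st$ea_error,
        skill_a = st$skill_a, skill_b = st$skill_b)

      if (length(o$members) >= 3) {
        fit <- tryCatch(
          fit_gaussian(o$members, alpha = alpha,
                       sd_convention = sd_convention),
          error = function(e) {
            note("%s year %d: %s", gl, o$year, conditionMessage(e))
            NULL
          })
        if (!is.null(fit)) {
          ir <- ignorance_score(o$observed, fit)
          scores[[length(scores) + 1L]] <- ir
          ign_rows[[length(ign_rows) + 1L]] <- data.frame(
            year = o$year, site = o$site, crop = o$crop,
            variable = o$variable, z = ir$z, score_bits = ir$score_bits,
            category = ir$category, normality_p = ir$normality_pvalue,
            valid = ir$valid)
        }
      } else {
        note("%s year %d: fewer than 3 members, not scored", gl, o$year)
      }
    }

    if (length(year_outcomes) >= 2) {
      ms <- multi_year_summary(year_outcomes,
                               closeness_band = closeness_band)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        site = g$site, crop = g$crop, variable = g$variable,
        n_years = ms$n_years,
        mean_ob = ms$mean[["OB"]], sd_ob = ms$sd[["OB"]],
        cv_ob = ms$cv[["OB"]],
        mean_cr = ms$mean[["CR"]], sd_cr = ms$sd[["CR"]],
        cv_cr = ms$cv[["CR"]],
        mean_ea = ms$mean[["EA"]], sd_ea = ms$sd[["EA"]],
        cv_ea = ms$cv[["EA"]],
        rmse_cr = ms$rmse_cr, rmse_ea = ms$rmse_ea,
        skill_a_cr = ms$skill$CR$skill_a, skill_b_cr = ms$skill$CR$skill_b,
        skill_a_ea = ms$skill$EA$skill_a, skill_b_ea = ms$skill$EA$skill_b)
    }

    n_valid <- sum(vapply(scores, function(r) isTRUE(r$valid), logical(1)))
    if (n_valid >= 2) {
      ss <- summarize_scores(scores,
                             high_score_threshold = high_score_threshold,
                             high_sigma_threshold = high_sigma_threshold)
      ign_sum_rows[[length(ign_sum_rows) + 1L]] <- data.frame(
        site = g$site, crop = g$crop, variable = g$variable,
        mean_score = ss$mean_score, sd_score = ss$sd_score,
        n_years = ss$n_years, n_excluded = ss$n_excluded, flag = ss$flag)
    } else if (length(scores)) {
      note("%s: fewer than 2 normality-passing years, no score summary", gl)
    }
  }

  bind <- function(lst, template) {
    if (length(lst)) { df <- do.call(rbind, lst); rownames(df) <- NULL; df }
    else template
  }
  list(
    verification = bind(ver_rows, data.frame()),
    summary = bind(sum_rows, data.frame()),
    ignorance = bind(ign_rows, data.frame()),
    ignorance_summary = bind(ign_sum_rows, data.frame()),
    warnings = warnings_log)
}

#' Verify an externally produced outcome table
#'
#' Runs the verification and Ignorance layers on a long-form outcome table
#' (\code{year,site,crop,realization,variable,value}; realizations
#' \code{OB}, optional \code{CR} and members \code{M01}...), e.g. one
#' produced by a genuine crop-model ensemble, without re-simulating.
#' Groups missing their OB value or holding fewer than two members are
#' skipped with a logged warning, never imputed.
#'
#' @param outcomes Path to a CSV outcome table, or an equivalent
#'   data.frame.
#' @param out_dir Optional directory for the report CSVs.
#' @param sd_convention,alpha,closeness_band,high_score_threshold,high_sigma_threshold
#'   Statistical options, as in \code{\link{experiment_config}}.
#' @return List with \code{verification}, \code{summary},
#'   \code{ignorance}, \code{ignorance_summary} data.frames,
#'   \code{warnings}, and \code{paths} when written.
#' @export
verify_from_table <- function(outcomes, out_dir = NULL,
                              sd_convention = "population", alpha = 0.05,
                              closeness_band = 2,
                              high_score_threshold = 4.21,
                              high_sigma_threshold = 2.0) {
  if (is.character(outcomes))
    outcomes <- utils::read.csv(outcomes, stringsAsFactors = FALSE)
  rep <- verify_outcome_table(outcomes, sd_convention = sd_convention,
                              alpha = alpha,
                              closeness_band = closeness_band,
                              high_score_threshold = high_score_threshold,
                              high_sigma_threshold = high_sigma_threshold)
  if (!nrow(rep$verification))
    stop("no verifiable (year, site, crop, variable) groups:\n  ",
         paste(rep$warnings, collapse = "\n  "))
  for (w in rep$warnings) warning(w, call. = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(verification = file.path(out_dir, "verification.csv"),
               summary = file.path(out_dir, "verification_summary.csv"),
               ignorance = file.path(out_dir, "ignorance.csv"),
               ignorance_summary = file.path(out_dir,
                                             "ignorance_summary.csv"))
    for (nm in names(paths))
      utils::write.csv(rep[[nm]], paths[[nm]], row.names = FALSE,
                       quote = FALSE)
    rep$paths <- paths
  }
  rep
}
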