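# Ignorance score of a standardized Gaussian at the score minimum (z = 0):
# -log2 phi(0) = 0.5 * log2(2*pi) ~= 1.3257 bits.
IGN_MIN_BITS <- 0.5 * log2(2 * pi)

#' Ignorance score of the standard Gaussian at a given z
#'
#' \code{-log2 phi(z) = 0.5*log2(2*pi) + z^2 / (2*ln 2)} bits. The category
#' boundaries used in interpretation are this function at |z| = 1 (~2.05,
#' printed 2.04) and |z| = 3 (~7.82, printed 7.81).
#'
#' @param z Standardized anomaly. Vectorised.
#' @return Score in bits.
#' @export
#' @examples
#' ignorance_at_z(0) # 1.3257...
#' ignorance_at_z(2) # 4.21
ignorance_at_z <- function(z) IGN_MIN_BITS + z^2 / (2 * log(2))

#' Interpretation thresholds of the Ignorance score
#'
#' Analytic boundary scores at one and three standard deviations,
#' \code{-log2 phi(1)} and \code{-log2 phi(3)}, together with the rounded
#' printed values (2.04 and 7.81 bits) conventionally used to call a
#' probabilistic forecast "very good" (score below the first) or "not
#' adequate" (score above the second), and the analytic probabilities of
#' falling below/above them for a perfectly calibrated Gaussian forecast.
#'
#' @return List with \code{analytic}, \code{printed} (each a named vector
#'   \code{very_good}/\code{not_adequate}) and \code{probabilities}.
#' @export
ignorance_thresholds <- function() {
  printed <- c(very_good = 2.04, not_adequate = 7.81)
  z_of <- function(s) sqrt((s - IGN_MIN_BITS) * 2 * log(2))
  list(
    analytic = c(very_good = ignorance_at_z(1),
                 not_adequate = ignorance_at_z(3)),
    printed = printed,
    probabilities = c(
      p_below_very_good = 2 * stats::pnorm(z_of(printed[["very_good"]])) - 1,
      p_above_not_adequate =
        2 * stats::pnorm(-z_of(printed[["not_adequate"]]))))
}

#' Construct a Gaussian fit directly
#'
#' Low-level constructor for a predictive Gaussian with known parameters
#' (e.g. the standard Gaussian for analytic work). For fitting ensemble
#' members use \code{\link{fit_gaussian}}.
#'
#' @param mu Mean.
#' @param sigma Standard deviation (> 0).
#' @param n Member count behind the fit (NA when analytic).
#' @param normality_pvalue,is_normal Normality screening results (NA when
#'   not screened).
#' @return An object of class \code{gaussian_fit}.
#' @export
gaussian_fit <- function(mu, sigma, n = NA_integer_,
                         normality_pvalue = NA_real_, is_normal = NA) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate Gaussian fit: sigma must be > 0")
  structure(list(mu = mu, sigma = sigma, n = n,
                 normality_pvalue = normality_pvalue,
                 is_normal = is_normal),
            class = "gaussian_fit")
}

#' Fit a Gaussian to ensemble member values, with normality screening
#'
#' Estimates mu as the member mean and sigma as the member standard
#' deviation (population, 1/N, convention by default, consistent with the
#' ensemble spread), and screens the members for Gaussianity with a
#' Shapiro--Wilk test. Years whose ensembles fail the screen are flagged
#' (\code{is_normal = FALSE}) so downstream summaries can exclude them;
#' they are never scored silently as if Gaussian.
#'
#' @param members Numeric vector of >= 3 member values.
#' @param alpha Significance level of the normality screen, in (0, 1).
#' @param sd_convention \code{"population"} (1/N, default) or
#'   \code{"sample"}.
#' @return A \code{\link{gaussian_fit}}.
#' @export
#' @examples
#' fit_gaussian(c(1, 2, 3))$sigma # sqrt(2/3)
fit_gaussian <- function(members, alpha = 0.05,
                         sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  if (length(members) < 3) stop("need at least 3 members to fit")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- length(members)
  mu <- mean(members)
  ss <- sum((members - mu)^2)
  sigma <- sqrt(ss / if (sd_convention == "population") n else n - 1)
  if (sigma == 0)
    stop("degenerate Gaussian fit: all members identical")
  pval <- stats::shapiro.test(members)$p.value
  gaussian_fit(mu, sigma, n = n, normality_pvalue = pval,
               is_normal = pval >= alpha)
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu %.4g, sigma %.4g, n %s, normality p %s\n",
              x$mu, x$sigma, x$n,
              if (is.na(x$normality_pvalue)) "-" else
                sprintf("%.3f", x$normality_pvalue)))
  invisible(x)
}

#' Ignorance score of an observation under a Gaussian ensemble fit
#'
#' Standardizes the verifying observation, \code{z = (y - mu)/sigma}, and
#' scores it against the standard Gaussian density:
#' \code{S = -log2 phi(z) = 0.5*log2(2*pi) + z^2/(2*ln 2)} bits. Lower is
#' better; the minimum is ~1.3257 bits at z = 0. Standardization makes the
#' score comparable across variables; \code{standardized = FALSE} gives
#' the raw-density variant \code{S + log2(sigma)} for single-variable use.
#' Categories use the printed thresholds: very good below 2.04 bits, not
#' adequate above 7.81 bits, acceptable between.
#'
#' @param y_obs Verifying (observation-based) value.
#' @param fit A non-degenerate \code{\link{gaussian_fit}}.
#' @param standardized Score the standardized density (default TRUE).
#' @return An object of class \code{ignorance_result}: list with \code{z},
#'   \code{score_bits}, \code{category}, \code{valid} (FALSE when the fit
#'   failed its normality screen) and \code{normality_pvalue}.
#' @export
#' @examples
#' ignorance_score(2, gaussian_fit(0, 1))$score_bits # 4.21
ignorance_score <- function(y_obs, fit, standardized = TRUE) {
  if (!inherits(fit, "gaussian_fit"))
    stop("fit must be a gaussian_fit")
  if (!is.finite(y_obs)) stop("y_obs must be finite")
  z <- (y_obs - fit$mu) / fit$sigma
  s <- ignorance_at_z(z)
  if (!standardized) s <- s + log2(fit$sigma)
  thr <- c(2.04, 7.81)
  category <- if (s < thr[1]) "very_good"
              else if (s > thr[2]) "not_adequate"
              else "acceptable"
  structure(list(z = z, score_bits = s, category = category,
                 valid = is.na(fit$is_normal) || isTRUE(fit$is_normal),
                 normality_pvalue = fit$normality_pvalue),
            class = "ignorance_result")
}

#' @export
print.ignorance_result <- function(x, ...) {
  cat(sprintf("<ignorance_result> z %+.3f, S %.3f bits (%s)%s\n",
              x$z, x$score_bits, x$category,
              if (isTRUE(x$valid)) "" else " [normality rejected]"))
  invisible(x)
}

#' Summarize Ignorance scores over years
#'
#' Mean score and its standard deviation (sample convention) over the
#' valid years, with the qualitative interpretation of the paper-style
#' rules made explicit: a high mean score with a low score sd flags the
#' chosen probability distribution as inadequate; a high mean with a high
#' sd flags some systematic effect disrupting the forecast or the
#' simulation.
#'
#' @param results List of \code{\link{ignorance_result}}s (one per year).
#' @param high_score_threshold Mean-score threshold in bits (default 4.21,
#'   the two-sigma boundary).
#' @param high_sigma_threshold Score-sd threshold in bits (default 2).
#' @return An object of class \code{score_summary}: list with
#'   \code{mean_score, sd_score, n_years, n_excluded, flag}.
#' @export
summarize_scores <- function(results, high_score_threshold = 4.21,
                             high_sigma_threshold = 2.0) {
  valid <- vapply(results, function(r) isTRUE(r$valid), logical(1))
  s <- vapply(results[valid], function(r) r$score_bits, numeric(1))
  if (length(s) < 2) stop("need at least 2 valid yearly scores")
  mean_s <- mean(s)
  sd_s <- stats::sd(s)
  flag <- if (mean_s > high_score_threshold) {
    if (sd_s <= high_sigma_threshold) "distribution_inadequate"
    else "systematic_disruption"
  } else "ok"
  structure(list(mean_score = mean_s, sd_score = sd_s,
                 n_years = length(s), n_excluded = sum(!valid),
                 flag = flag),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf(
    "<score_summary> S mean %.3f bits, sd %.3f, %d years (%d excluded): %s\n",
    x$mean_score, x$sd_score, x$n_years, x$n_excluded, x$flag))
  invisible(x)
}
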