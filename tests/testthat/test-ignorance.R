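test_that("Gaussian fit uses the population sigma and screens normality", {
  fit <- fit_gaussian(c(1, 2, 3))
  expect_equal(fit$mu, 2)
  expect_equal(fit$sigma, sqrt(2 / 3))
  expect_equal(fit_gaussian(c(1, 2, 3), sd_convention = "sample")$sigma, 1)
  expect_error(fit_gaussian(c(1, 1, 1)), "degenerate")
  expect_error(fit_gaussian(c(1, 2)), "at least 3")
})

test_that("the normality screen accepts genuinely Gaussian ensembles", {
  ok <- vapply(1:200, function(s) {
    x <- with_seed_local(s, rnorm(50))
    fit_gaussian(x)$is_normal
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("score anchors at z = 0, 2, 3 match the analytic boundary values", {
  std <- gaussian_fit(0, 1)
  expect_equal(ignorance_score(0, std)$score_bits, 0.5 * log2(2 * pi),
               tolerance = 1e-12)
  expect_equal(ignorance_score(2, std)$score_bits, 4.21, tolerance = 0.01)
  s3 <- ignorance_score(3, std)$score_bits
  expect_gte(s3, 7.81)
  expect_equal(s3, 7.82, tolerance = 0.01)
  # scoring through the formula equals -log2 of the density
  expect_equal(ignorance_score(1.3, std)$score_bits,
               -log2(dnorm(1.3)), tolerance = 1e-12)
})

test_that("score categories follow the printed 2.04/7.81 thresholds", {
  std <- gaussian_fit(0, 1)
  expect_equal(ignorance_score(0.5, std)$category, "very_good")
  expect_equal(ignorance_score(2, std)$category, "acceptable")
  expect_equal(ignorance_score(3.1, std)$category, "not_adequate")
  thr <- ignorance_thresholds()
  expect_equal(unname(thr$printed), c(2.04, 7.81))
  expect_equal(unname(thr$analytic), c(-log2(dnorm(1)), -log2(dnorm(3))),
               tolerance = 1e-12)
})

test_that("the score is even, convex and minimal at z = 0", {
  z <- seq(-4, 4, by = 0.25)
  s <- ignorance_at_z(z)
  expect_equal(s, rev(s))                      # even
  expect_true(all(diff(s[z >= 0]) > 0))        # increasing in |z|
  expect_true(all(diff(diff(s)) > -1e-12))     # convex
  expect_equal(min(s), 0.5 * log2(2 * pi))
  expect_equal(round(min(s), 4), 1.3257)
})

test_that("the score is invariant under joint shift and rescale", {
  members <- c(2.5, 3.1, 2.9, 3.6, 2.2, 3.3, 2.8)
  y <- 3.0
  base <- ignorance_score(y, fit_gaussian(members))
  shifted <- ignorance_score(y + 7, fit_gaussian(members + 7))
  scaled <- ignorance_score(y * 4, fit_gaussian(members * 4))
  expect_equal(shifted$z, base$z, tolerance = 1e-9)
  expect_equal(scaled$z, base$z, tolerance = 1e-9)
  expect_equal(shifted$score_bits, base$score_bits, tolerance = 1e-9)
  expect_equal(scaled$score_bits, base$score_bits, tolerance = 1e-9)
  # raw-density variant differs by log2(sigma)
  fit <- fit_gaussian(members)
  expect_equal(ignorance_score(y, fit, standardized = FALSE)$score_bits,
               base$score_bits + log2(fit$sigma), tolerance = 1e-12)
})

test_that("a calibrated Gaussian forecast scores below 2.04 with probability 0.68", {
  # closed form: S < t iff |z| < z(t)
  z_t <- sqrt((2.04 - 0.5 * log2(2 * pi)) * 2 * log(2))
  p <- 2 * pnorm(z_t) - 1
  expect_equal(p, 0.68, tolerance = 0.005 / 0.68)
})

test_that("score summaries flag inadequate distributions and disruptions", {
  mk <- function(s) structure(list(z = 0, score_bits = s, category = "x",
                                   valid = TRUE, normality_pvalue = 0.5),
                              class = "ignorance_result")
  ok <- summarize_scores(lapply(c(2.0, 2.1, 1.9), mk))
  expect_equal(ok$flag, "ok")
  expect_equal(ok$mean_score, 2.0)

  inad <- summarize_scores(lapply(c(6.0, 6.1, 5.9), mk))
  expect_equal(inad$flag, "distribution_inadequate")

  disr <- summarize_scores(lapply(c(2.0, 10.0, 6.0), mk))
  expect_equal(disr$flag, "systematic_disruption")

  # normality-rejected years are excluded and counted
  bad <- structure(list(z = 0, score_bits = 50, category = "x",
                        valid = FALSE, normality_pvalue = 0.001),
                   class = "ignorance_result")
  sm <- summarize_scores(c(lapply(c(2.0, 2.1), mk), list(bad)))
  expect_equal(sm$n_excluded, 1)
  expect_equal(sm$n_years, 2)
  expect_error(summarize_scores(list(mk(2), bad)), "2 valid")
})
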