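test_that("truth generation is deterministic and physically bounded", {
  cfg <- test_climate()
  a <- generate_truth(cfg, 2006, seed = 11)
  b <- generate_truth(cfg, 2006, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_truth(cfg, 2006, seed = 12)))

  for (seed in 1:5) {
    ws <- generate_truth(cfg, 2005 + seed, seed = seed)
    expect_equal(nrow(ws), 215) # 1 Mar - 1 Oct always holds 215 days
    expect_true(all(ws$tmax >= ws$tmin))
    expect_true(all(ws$precip >= 0))
    expect_true(all(ws$rhum >= 0 & ws$rhum <= 100))
    expect_true(all(ws$srad >= 0))
    expect_true(all(diff(as.integer(as.Date(ws$date))) == 1))
  }
})

test_that("a degenerate config produces a constant temperature series", {
  cfg <- test_climate(temp_noise_sd = 0, temp_amplitude = 0,
                      temp_mean = 15, diurnal_range = 10)
  ws <- generate_truth(cfg, 2010, seed = 3)
  expect_true(all(ws$tmax == 20))
  expect_true(all(ws$tmin == 10))
})

test_that("wet-day frequency converges to the Markov stationary value", {
  cfg <- test_climate(p01 = 0.25, p11 = 0.55)
  wet <- unlist(lapply(1:50, function(s) {
    generate_truth(cfg, 2006, seed = s)$precip > 0
  })) # 50 x 215 = 10750 days
  expect_equal(mean(wet), stationary_wet_frequency(0.25, 0.55),
               tolerance = 0.02 / stationary_wet_frequency(0.25, 0.55))
})

test_that("mean season-total precipitation matches its analytic expectation", {
  cfg <- test_climate()
  totals <- vapply(1:200, function(s)
    sum(generate_truth(cfg, 2006, seed = s)$precip), numeric(1))
  expected <- stationary_wet_frequency(cfg$p01, cfg$p11) * 215 *
    cfg$gamma_shape * cfg$gamma_scale
  expect_equal(mean(totals), expected, tolerance = 0.05)
})

test_that("zero bias and zero inflation reproduce truth in control and members", {
  cfg <- test_climate(member_inflation = 0)
  truth <- generate_truth(cfg, 2006, seed = 5)
  ens <- perturb_members(truth, 4, cfg, seed = 6)
  for (m in c(list(ens$control), ens$members)) {
    expect_equal(m$tmax, truth$tmax)
    expect_equal(m$tmin, truth$tmin)
    expect_equal(m$precip, truth$precip)
  }
})

test_that("a pure temperature bias shifts every member day by exactly the bias", {
  cfg <- test_climate(member_inflation = 0, member_temp_bias = 1)
  truth <- generate_truth(cfg, 2006, seed = 5)
  ens <- perturb_members(truth, 3, cfg, seed = 6)
  expect_equal(ens$control$tmax - truth$tmax, rep(1, nrow(truth)))
  for (m in ens$members) {
    expect_equal(m$tmax - truth$tmax, rep(1, nrow(truth)))
    expect_equal(m$tmin - truth$tmin, rep(1, nrow(truth)))
    expect_equal(m$tmax - m$tmin, truth$tmax - truth$tmin)
  }
})

test_that("a multiplicative precipitation bias is recovered across members", {
  # members keep truth's wet-day pattern here so the Monte Carlo average
  # isolates the bias knob
  cfg <- test_climate(member_precip_bias = 1.2,
                      member_occurrence_decoupling = 0)
  truth <- generate_truth(cfg, 2006, seed = 21)
  ens <- perturb_members(truth, 50, cfg, seed = 22)
  ratio <- mean(member_precip_totals(ens)) / sum(truth$precip)
  expect_equal(ratio, 1.2, tolerance = 0.05 / 1.2)
})

test_that("members are pairwise distinct when inflation is positive and valid series", {
  cfg <- test_climate()
  truth <- generate_truth(cfg, 2006, seed = 31)
  ens <- perturb_members(truth, 6, cfg, seed = 32)
  tot <- member_precip_totals(ens)
  expect_equal(length(unique(tot)), 6)
  for (m in ens$members) expect_silent(validate_weather_series(m))
  expect_error(perturb_members(truth, 1, cfg, seed = 1), "n_members")
})

test_that("ensemble generation is reproducible under a fixed seed", {
  cfg <- test_climate()
  truth <- generate_truth(cfg, 2006, seed = 41)
  e1 <- perturb_members(truth, 5, cfg, seed = 42)
  e2 <- perturb_members(truth, 5, cfg, seed = 42)
  expect_identical(e1, e2)
})

test_that("weather CSV round-trips through the documented schema", {
  cfg <- test_climate()
  ws <- generate_truth(cfg, 2006, seed = 7, site_id = "s1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(ws, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "date,tmax,tmin,rhum,wind,srad,precip,realization")
  back <- read_weather_csv(path, site_id = "s1", latitude = cfg$latitude)
  expect_equal(attr(back, "realization"), "OB")
  expect_equal(back$precip, ws$precip, tolerance = 1e-9)
  expect_equal(as.Date(back$date), as.Date(ws$date))
})

test_that("member count mapping falls back and the default ramp spans 10..50", {
  ramp <- default_member_ramp()
  expect_equal(ramp[["2006"]], 10L)
  expect_equal(ramp[["2014"]], 50L)
  cfg <- test_climate(members_per_year = ramp, default_members = 12)
  expect_equal(members_for_year(cfg, 2010), ramp[["2010"]])
  expect_equal(members_for_year(cfg, 1999), 12L)
  expect_error(test_climate(members_per_year = list(`2006` = 1)), ">= 2")
})
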