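test_that("daily growing degree-days follow the clipped mean formula", {
  expect_equal(gdd(30, 20, 10), 15)
  expect_equal(gdd(12, 6, 10), 0)
  expect_equal(gdd(35, 15, 10), 15) # mean unchanged by diurnal spread
  expect_error(gdd(10, 20, 5), "tmax")
})

test_that("a hand-stepped three-day toy season is reproduced exactly", {
  # constant gdd 10/day, requirement 30 -> maturity on day 3; soil held
  # near FC (full bucket, TAW 160 mm, max depletion 15 < RAW 80);
  # et0 fixed at 5, Kcb 1, Ke 0, WP* 15, HI 0.5:
  # Tr 5 mm/day, sum ET 15 mm, biomass 3*15 g/m2 = 0.45 t/ha,
  # yield 0.225 t/ha
  crop <- test_crop(gdd_requirement = 30, tbase = 10,
                    kcb_stages = c(1, 1, 1, 1), ke_soil = 0,
                    wp_star = 15, hi = 0.5, planting_doy = 1,
                    depletion_p = 0.5)
  soil <- test_soil(initial_fill = 1)
  ws <- toy_weather(3, tmax = 25, tmin = 15, et0 = 5)
  res <- run_season(ws, crop, soil)
  expect_true(res$matured)
  expect_equal(res$lgp, 3)
  expect_equal(res$transpiration_sum, 15)
  expect_equal(res$et_sum, 15)
  expect_equal(res$biomass, 0.45)
  expect_equal(res$yield, 0.225)
  expect_equal(res$season_precip, 0)
})

test_that("no water means no transpiration and no yield", {
  crop <- test_crop(planting_doy = 1)
  soil <- test_soil(initial_fill = 0)
  ws <- toy_weather(60, precip = 0)
  res <- run_season(ws, crop, soil)
  expect_equal(res$transpiration_sum, 0)
  expect_equal(res$yield, 0)
  expect_equal(res$biomass, 0)
})

test_that("the surrogate is deterministic and errors before planting", {
  cfg <- test_climate()
  ws <- generate_truth(cfg, 2006, seed = 2)
  crop <- test_crop()
  soil <- test_soil()
  expect_identical(run_season(ws, crop, soil), run_season(ws, crop, soil))
  expect_error(run_season(ws, test_crop(planting_doy = 300), soil),
               "planting")
})

test_that("seasonal water balance closes to numerical precision", {
  cfg <- test_climate()
  crop <- test_crop()
  soil <- test_soil()
  for (seed in 1:10) {
    ws <- generate_truth(cfg, 2005 + seed, seed = seed)
    res <- run_season(ws, crop, soil)
    expect_lt(abs(water_balance_residual(res)), 1e-6)
    expect_gte(res$et_sum, res$transpiration_sum)
    expect_gte(res$transpiration_sum, 0)
  }
})

test_that("yield is non-decreasing in the initial soil fill", {
  cfg <- test_climate(gamma_scale = 3) # drier season, water-limited
  ws <- generate_truth(cfg, 2006, seed = 13)
  crop <- test_crop()
  fills <- c(0, 0.25, 0.5, 0.75, 1)
  yields <- vapply(fills, function(f)
    run_season(ws, crop, test_soil(initial_fill = f))$yield, numeric(1))
  expect_true(all(diff(yields) >= -1e-12))
  expect_gt(yields[5], yields[1])
})

test_that("yield-to-biomass ratio equals the harvest index exactly", {
  cfg <- test_climate()
  crop <- test_crop(hi = 0.37)
  soil <- test_soil()
  for (seed in 1:5) {
    res <- run_season(generate_truth(cfg, 2006, seed = seed), crop, soil)
    expect_gt(res$biomass, 0)
    expect_equal(res$yield / res$biomass, 0.37, tolerance = 1e-12)
  }
})

test_that("warmer ensemble members mature no later than truth", {
  cfg_warm <- test_climate(member_temp_bias = 2, member_inflation = 0)
  crop <- test_crop()
  soil <- test_soil()
  for (seed in 1:5) {
    truth <- generate_truth(cfg_warm, 2006, seed = seed)
    ens <- perturb_members(truth, 3, cfg_warm, seed = seed + 100)
    lgp_truth <- run_season(truth, crop, soil)$lgp
    for (m in ens$members)
      expect_lte(run_season(m, crop, soil)$lgp, lgp_truth)
  }
})

test_that("crop and soil parameter fixtures load and validate", {
  crops_dir <- system.file("extdata", "crops", package = "greencast")
  for (f in list.files(crops_dir, full.names = TRUE)) {
    cp <- read_crop_params(f)
    expect_s3_class(cp, "crop_params")
  }
  sites_dir <- system.file("extdata", "sites", package = "greencast")
  for (f in list.files(sites_dir, full.names = TRUE)) {
    expect_s3_class(read_soil_params(f), "soil_params")
    expect_s3_class(read_climate_config(f), "climate_config")
  }
  expect_error(soil_params(0.4, 0.5, 0.6), "wp < fc")
  expect_error(test_crop(stage_fractions = c(0.5, 0.4, 0.8)),
               "stage_fractions")
})
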