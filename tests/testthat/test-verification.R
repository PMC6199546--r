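test_that("per-year RMSE and spread match hand arithmetic", {
  o <- ensemble_outcome(2006, "s", "c", "yield", c(1, 2, 3), observed = 2)
  expect_equal(year_rmse(o), sqrt(2 / 3))
  expect_equal(year_spread(o), sqrt(2 / 3)) # EA equals OB: ideal ensemble

  o2 <- ensemble_outcome(2006, "s", "c", "yield", c(2, 4, 6), observed = 3)
  expect_equal(year_rmse(o2), sqrt(11 / 3))
  expect_equal(year_spread(o2), sqrt(8 / 3))

  perfect <- ensemble_outcome(2006, "s", "c", "yield", c(2, 2, 2),
                              observed = 2)
  expect_equal(year_rmse(perfect), 0)
  expect_equal(year_spread(perfect), 0)

  expect_error(ensemble_outcome(2006, "s", "c", "yield", 3, observed = 2),
               "2 ensemble members")
})

test_that("rmse^2 decomposes exactly into sprd^2 plus the squared EA error", {
  with_seed_local(7, {
    for (i in 1:200) {
      n <- sample(2:50, 1)
      o <- ensemble_outcome(2006, "s", "c", "precip",
                            rnorm(n, sd = runif(1, 0.1, 10)),
                            observed = rnorm(1, sd = 5))
      rmse <- year_rmse(o)
      sprd <- year_spread(o)
      ea_err <- o$ensemble_average - o$observed
      expect_equal(rmse^2, sprd^2 + ea_err^2, tolerance = 1e-9)
      expect_gte(rmse, sprd)
    }
  })
})

test_that("member order and duplication leave RMSE and spread unchanged", {
  y <- c(3.2, 1.1, 4.8, 2.5, 0.7)
  o <- ensemble_outcome(2006, "s", "c", "et", y, observed = 2)
  op <- ensemble_outcome(2006, "s", "c", "et", rev(y), observed = 2)
  od <- ensemble_outcome(2006, "s", "c", "et", c(y, y), observed = 2)
  expect_equal(year_rmse(op), year_rmse(o))
  expect_equal(year_spread(op), year_spread(o))
  expect_equal(year_rmse(od), year_rmse(o))  # 1/N convention
  expect_equal(year_spread(od), year_spread(o))
})

test_that("Pielke criteria follow their definitions", {
  sk <- pielke_skill(0.5, 1.0, 1.0)
  expect_true(sk$skill_a)
  expect_true(sk$skill_b) # ratio 1 inside any band
  expect_false(pielke_skill(0.5, 0.4, 1.0, closeness_band = 2)$skill_b)
  expect_false(pielke_skill(1.5, 1.0, 1.0)$skill_a)
  expect_error(pielke_skill(1, 1, 0), "sigma_obs")
  expect_error(pielke_skill(1, 1, 1, closeness_band = 0.5),
               "closeness_band")
})

test_that("multi-year summary uses the sample convention and cross-year RMSE", {
  mk <- function(year, ob, cr, ea_members) {
    ensemble_outcome(year, "s", "c", "yield", ea_members, control = cr,
                     observed = ob)
  }
  # OB = {2, 4}: mean 3, sample sd sqrt(2), cv sqrt(2)/3;
  # CR = OB + 1 -> RMSE(CR) = 1; EA = OB (members symmetric around OB)
  # -> RMSE(EA) = 0
  outs <- list(mk(2006, 2, 3, c(1, 3)), mk(2007, 4, 5, c(3, 5)))
  ms <- multi_year_summary(outs)
  expect_equal(ms$mean[["OB"]], 3)
  expect_equal(ms$sd[["OB"]], sqrt(2))
  expect_equal(ms$cv[["OB"]], sqrt(2) / 3)
  expect_equal(ms$rmse_cr, 1)
  expect_equal(ms$rmse_ea, 0)
  expect_error(multi_year_summary(outs[1]), "2 years")
})

test_that("ensemble-mean error obeys the (N+1)/N spread-skill relation when calibrated", {
  # members and observation drawn from the same distribution: over many
  # years E[(EA - OB)^2] = (1 + 1/N) * E[sample spread^2]
  n_members <- 10
  n_years <- 2000
  with_seed_local(99, {
    ea_err2 <- sprd2 <- numeric(n_years)
    for (i in seq_len(n_years)) {
      o <- ensemble_outcome(2006, "s", "c", "yield", rnorm(n_members),
                            observed = rnorm(1))
      sprd2[i] <- year_spread(o, convention = "sample")^2
      ea_err2[i] <- (o$ensemble_average - o$observed)^2
    }
  })
  ratio <- mean(ea_err2) / mean(sprd2)
  expect_equal(ratio, (n_members + 1) / n_members, tolerance = 0.1)
})
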