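test_that("20-s binning averages and truncates correctly", {
  gs <- gas_series(seq(0.5, 59.5, by = 1), rep(1000, 60), rep(900, 60),
                   condition = "exercise")
  b <- bin_20s(gs)
  expect_equal(nrow(b), 2L)  # last sample at 59.5 spans 59 s -> 2 full bins
  expect_equal(b$vo2, c(1000, 1000))
  expect_equal(b$rer, c(0.9, 0.9))

  gs2 <- gas_series(seq(0.5, 69.5, by = 1), rep(1000, 70), rep(900, 70),
                    condition = "exercise")
  expect_equal(nrow(bin_20s(gs2)), 3L)  # trailing 9 s dropped

  expect_error(bin_20s(gas_series(c(1, 5), c(10, 10), c(9, 9),
                                  condition = "exercise")),
               class = "metflexr_insufficient_data")
})

test_that("bin means equal brute-force masked means on a noisy test", {
  rmp <- generate_ramp(2200, 16.7, 90, seed = 51, noise_cv = 0.05)
  s <- rmp$series$samples
  b <- bin_20s(rmp$series)
  t0 <- s$t[1]
  for (k in sample(nrow(b), 10)) {
    mask <- s$t >= b$t_start[k] & s$t < b$t_end[k]
    expect_equal(b$vo2[k], mean(s$vo2[mask]))
    expect_equal(b$rer[k], mean(s$vco2[mask]) / mean(s$vo2[mask]))
  }
})

test_that("VO2max is the best 20-s bin, scaled per kg and per kg FFM", {
  rmp <- generate_ramp(2120, 16.7, 93.2, seed = 52, noise_cv = 0)
  b <- bin_20s(rmp$series)
  fit <- vo2max(b, 93.2, ffm = 55, stages = rmp$stages)
  expect_equal(fit$vo2max_ml_min, 2120)
  expect_equal(fit$vo2max_ml_kg_min, 2120 / 93.2)
  expect_equal(round(fit$vo2max_ml_kg_min, 2), 22.75)
  expect_gte(fit$vo2max_ml_kgffm_min, fit$vo2max_ml_kg_min)
  expect_equal(fit$max_po_w, max(rmp$stages$power_w))

  # brute-force max over random noisy tests
  for (s in 1:20) {
    rr <- generate_ramp(2000, 17, 85, seed = 600 + s, noise_cv = 0.03)
    bb <- bin_20s(rr$series)
    expect_equal(vo2max(bb, 85)$vo2max_ml_min, max(bb$vo2))
  }
})

test_that("planted VO2max plateau is recovered within bin noise", {
  errs <- vapply(1:100, function(s) {
    rr <- generate_ramp(2120, 16.7, 90, seed = 700 + s, noise_cv = 0.02)
    vo2max(bin_20s(rr$series), 90)$vo2max_ml_min - 2120
  }, numeric(1))
  # plateau-bin means carry sd ~ 2%/sqrt(7); the max statistic stays within
  # a few bin SDs of the plant and its mean error within one bin SD
  bin_sd <- 2120 * 0.02 / sqrt(7)
  expect_lt(max(abs(errs)), 4 * bin_sd)
  expect_lt(abs(mean(errs)), bin_sd)
})

test_that("exercise ΔRER follows the stage convention", {
  rmp <- generate_ramp(2120, 16.7, 93.2, rer_low = 0.74, rer_max = 1.12,
                       seed = 53, noise_cv = 0)
  b <- bin_20s(rmp$series)
  stages <- rmp$stages
  low <- stage_summary(b, stages[stages$power_w == 25, ])
  mx <- stage_summary(b, stages[nrow(stages), ])
  ext <- rer_extrema(b, low, mx)
  expect_equal(ext$delta_rer_ex, 0.38, tolerance = 1e-9)
  expect_equal(ext$rer_low_ex, 0.74, tolerance = 1e-9)
  expect_equal(ext$rer_max_ex, 1.12, tolerance = 1e-9)
  expect_lte(ext$rer_min, ext$rer_low_ex + 1e-12)
  # extrema convention on a constant test gives zero delta
  cgs <- gas_series(seq(0.5, 199.5), rep(1000, 200), rep(800, 200),
                    condition = "exercise")
  cb <- bin_20s(cgs)
  expect_equal(rer_extrema(cb, convention = "extrema")$delta_rer_ex, 0)
})

test_that("planted stage ΔRER survives 2% breath noise", {
  errs <- vapply(1:60, function(s) {
    rr <- generate_ramp(2120, 16.7, 93.2, rer_low = 0.74, rer_max = 1.12,
                        seed = 800 + s, noise_cv = 0.02)
    b <- bin_20s(rr$series)
    low <- stage_summary(b, rr$stages[rr$stages$power_w == 25, ])
    mx <- stage_summary(b, rr$stages[nrow(rr$stages), ])
    rer_extrema(b, low, mx)$delta_rer_ex - 0.38
  }, numeric(1))
  # stage-tail means hold ~20 breaths at 2% ratio noise (sd ~ 0.006 per
  # stage difference): the estimator is unbiased within 0.005 and single
  # tests scatter within a few noise SDs
  expect_lt(abs(mean(errs)), 0.005)
  expect_lt(max(abs(errs)), 0.025)
})

test_that("stage substrate delegates to the labeled coefficient sets", {
  st <- list(power_w = 25, mean_vo2 = 601, mean_vco2 = 471, rer = 471 / 601)
  low <- stage_substrate(st, "low_intensity", 93.2)
  expect_equal(round(low$choox_mg_kg_min, 1), 2.2)
  mx <- stage_substrate(st, "maximal", 93.2)
  # coefficient deltas show up directly on identical gas input
  expect_equal(low$choox_g_min - mx$choox_g_min,
               (4.344 - 4.210) * 0.471 + (-3.061 + 2.962) * 0.601)
  expect_error(stage_substrate(st, "sprint", 93.2))
})

test_that("delta efficiency implements 100×ΔPO×0.014/ΔEE with sex bounds", {
  mk <- function(p, ee) {
    # invert the low-intensity EE equation at RER 0.9
    vo2 <- 1000 * ee / (0.575 * 0.9 + 4.435)
    list(power_w = p, mean_vo2 = vo2, mean_vco2 = 0.9 * vo2, rer = 0.9)
  }
  # ΔPO 50 W between 25 and 75 W, EE 2.9 -> 7.09 kcal/min
  eff <- delta_efficiency(list(mk(25, 2.9), mk(75, 7.09)), sex = "female")
  expect_equal(eff, 100 * (50 * 0.014) / (7.09 - 2.9))
  expect_equal(eff, 16.7, tolerance = 0.01)
  # EE rise exactly 0.014 per watt -> 100%
  expect_equal(delta_efficiency(list(mk(25, 2.9), mk(100, 2.9 + 75 * 0.014)),
                                sex = "male"), 100)
  # scale invariance of the ratio
  e1 <- delta_efficiency(list(mk(25, 3), mk(75, 5)), sex = "female")
  e2 <- delta_efficiency(list(mk(25, 3), mk(125, 7)), sex = "female",
                         bounds_w = c(25, 125))
  expect_equal(e1, e2)
  expect_error(delta_efficiency(list(mk(25, 3)), sex = "male"),
               class = "metflexr_not_computable")
  expect_error(delta_efficiency(list(mk(25, 3), mk(75, 2.5)), sex = "female"),
               class = "metflexr_degenerate_input")
})

test_that("planted efficiency is recovered through the full exercise path", {
  errs <- vapply(1:40, function(s) {
    rr <- generate_ramp(2400, 16.7, 95, seed = 900 + s, noise_cv = 0.02)
    b <- bin_20s(rr$series)
    stg <- rr$stages
    low <- stage_summary(b, stg[stg$power_w == 25, ])
    hi <- stage_summary(b, stg[stg$power_w == 100, ])
    delta_efficiency(list(low, hi), sex = "male") - 16.7
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.3)
  expect_lt(max(abs(errs)), 1.2)
})
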