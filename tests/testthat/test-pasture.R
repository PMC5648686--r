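wp_lin <- wastage_params("linear", p_wi_1 = 0, p_wi_2 = 0.7,
                         p_su_1 = 5.7, p_su_2 = 9.6)

test_that("relative wastage interpolates linearly between its anchors", {
  expect_equal(relative_wastage(wp_lin, 0, "su"), 5.7)
  expect_equal(relative_wastage(wp_lin, 1000, "su"), 9.6)
  expect_equal(relative_wastage(wp_lin, 500, "su"), 7.65)
  # extrapolation above 1000 kg/ha stays linear
  expect_equal(relative_wastage(wp_lin, 2000, "su"), 5.7 + 3.9 * 2)
  # spring and autumn are tied to half the summer value at every biomass
  for (z in c(0, 137, 1000, 1800))
    expect_equal(relative_wastage(wp_lin, z, "sp"),
                 0.5 * relative_wastage(wp_lin, z, "su"))
  expect_error(relative_wastage(wp_lin, -1, "su"), "negative")
  wc <- wastage_params("constant", p_wi_1 = 0.5, p_su_1 = 8.5)
  expect_equal(relative_wastage(wc, 0, "wi"), relative_wastage(wc, 1500, "wi"))
  expect_error(wastage_params("linear", p_wi_1 = -0.1, p_su_1 = 2))
})

test_that("infrastructure wastage is proportional, anchored at 25% -> 1", {
  expect_equal(infra_wastage(25), 1)
  expect_equal(infra_wastage(27.2), 1.088)
  expect_equal(infra_wastage(2.5), 0.1)
  expect_error(infra_wastage(101))
  expect_error(infra_wastage(-1))
})

test_that("heavy-metal bands map to growth multipliers", {
  expect_equal(heavy_metal_multiplier(">15"), 0.4)
  expect_equal(heavy_metal_multiplier("9-12"), 0.6)
  expect_equal(heavy_metal_multiplier("3-6"), 0.8)
  expect_equal(heavy_metal_multiplier("none"), 1.0)
  expect_equal(heavy_metal_multiplier(c(1, 5, 10, 20)), c(1, 0.8, 0.6, 0.4))
  expect_warning(m <- heavy_metal_multiplier("mystery"), "unknown")
  expect_equal(m, 1.0)
})

test_that("annual growth is logistic, scaled by habitat and heavy metals", {
  cfg <- grazing_config()
  expect_equal(annual_growth(cfg$K, 1, 1, cfg), 0)
  z <- 800
  expect_equal(annual_growth(z, 0.5, 1, cfg), 0.5 * annual_growth(z, 1, 1, cfg))
  expect_equal(annual_growth(z, 1, 0.4, cfg), 0.4 * annual_growth(z, 1, 1, cfg))
  # never grows past carrying capacity
  expect_lte(z + annual_growth(z, 1, 1, grazing_config(r0 = 20)), cfg$K)
  gom <- grazing_config(growth = "gompertz")
  expect_equal(annual_growth(0, 1, 1, gom), 0)
  expect_gt(annual_growth(800, 1, 1, gom), 0)
})

test_that("seasonal removal is intake times one plus wastage, clamped at z", {
  cfg <- grazing_config()
  st <- pasture_state(z = 400, area = 1000)
  # constant wastage 1 and no infrastructure: consumption = 2 x intake
  w1 <- wastage_params("constant", p_wi_1 = 1, p_su_1 = 1)
  out <- seasonal_removal(st, 1e5, "wi", w1, infra_pct = 0, config = cfg)
  expect_equal(out$removal, 2 * out$intake_per_ha)
  expect_equal(out$wastage_mult, 1)
  # nothing to graze
  st0 <- pasture_state(z = 0, area = 1000)
  out0 <- seasonal_removal(st0, 1e5, "su", wp_lin)
  expect_equal(out0$removal, 0)
  # clamping: tiny biomass, huge pressure -> removal equals z exactly
  sts <- pasture_state(z = 1, area = 100)
  outc <- seasonal_removal(sts, 1e6, "su", wp_lin)
  expect_true(outc$clamped)
  expect_equal(outc$removal, 1)
  # hand oracle for an unclamped step
  z <- 300; rd <- 5000; area <- 2000
  gi <- 0.4 * z / (z + 300)
  W <- 5.7 + 3.9 * z / 1000
  expect_equal(seasonal_removal(pasture_state(z, area), rd, "su", wp_lin)$removal,
               gi * (1 + W) * rd / area)
})

test_that("feed and arboreal substitution reduce winter ground intake", {
  cfg <- grazing_config()
  st <- pasture_state(z = 400, area = 1000, arboreal_pool = 0)
  base <- seasonal_removal(st, 1e5, "wi", wp_lin, config = cfg)
  fed <- seasonal_removal(st, 1e5, "wi", wp_lin, config = cfg, feeding_kg = 100)
  expect_lt(fed$removal, base$removal)
  expect_equal(fed$ground_daily, base$ground_daily - 100 * 0.8 / 180)
  stq <- pasture_state(z = 400, area = 1000, arboreal_pool = 5e4)
  arb <- seasonal_removal(stq, 1e5, "wi", wp_lin, config = cfg)
  expect_lt(arb$removal, base$removal)
  expect_equal(arb$arboreal_daily, 0.5)  # pool / reindeer-days, below cap
})

test_that("ungrazed pastures grow monotonically toward carrying capacity", {
  rec <- one_district(z1995 = 50, g = 1)
  hs <- data.frame(year = 1995:2007, rd_wi = 0, rd_sp = 0, rd_su = 0, rd_au = 0)
  traj <- simulate_lichen(rec, hs, wp_lin)
  expect_equal(nrow(traj), 14)
  expect_true(all(diff(traj$z) > 0))
  expect_lte(max(traj$z), grazing_config()$K)
})

test_that("higher wastage weakly decreases final biomass; rotation shields summer", {
  ds <- tiny_ds(5, seed = 9)
  rec <- ds$districts[1, ]
  hs <- corrected_herd(ds, rec$district_id)
  base <- simulate_lichen(rec, hs, wp_lin)
  up <- simulate_lichen(rec, hs, wastage_params("linear", 0.3, 1.0, 6.7, 10.6))
  expect_lte(up$z[14], base$z[14])
  # constant-form parameters expressed through the linear form match exactly
  wc <- wastage_params("constant", p_wi_1 = 0.5, p_su_1 = 8.5)
  wl_as_const <- wastage_params("linear", p_wi_1 = 0.5, p_wi_2 = 0.5,
                                p_su_1 = 8.5, p_su_2 = 8.5)
  expect_identical(simulate_lichen(rec, hs, wc)$z,
                   simulate_lichen(rec, hs, wl_as_const)$z)
  # a rotating district's summer removal from the winter range is exactly 0
  rot <- rec; rot$rotation <- TRUE
  traj <- simulate_lichen(rot, hs, wp_lin, detail = TRUE)
  det <- attr(traj, "detail")
  expect_true(all(det$removal[det$season %in% c("su", "au")] == 0))
})

test_that("per-season ledger conserves biomass: removal = intake x (1 + W)", {
  ds <- tiny_ds(4, seed = 17)
  rec <- ds$districts[2, ]
  hs <- corrected_herd(ds, rec$district_id)
  traj <- simulate_lichen(rec, hs, wp_lin, detail = TRUE)
  det <- attr(traj, "detail")
  expect_equal(det$removal, det$intake * (1 + det$wastage), tolerance = 1e-9)
})

test_that("the compiled kernel agrees with the reference simulator", {
  ds <- tiny_ds(6, seed = 23)
  inputs <- reinpast:::.sim_inputs(ds)
  set.seed(5)
  for (k in 1:5) {
    p <- c(runif(2, 0, 1.5), runif(2, 2, 12))
    pred_cpp <- reinpast:::.predict_z2008(inputs, p)
    wp <- wastage_params("linear", p[1], p[2], p[3], p[4])
    pred_r <- vapply(seq_len(6), function(i) {
      hs <- corrected_herd(ds, ds$districts$district_id[i])
      traj <- simulate_lichen(ds$districts[i, ], hs, wp)
      traj$z[nrow(traj)]
    }, numeric(1))
    expect_equal(pred_cpp, pred_r, tolerance = 1e-12)
  }
})
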