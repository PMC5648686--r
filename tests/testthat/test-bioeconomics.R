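wl <- wastage_params("linear", p_wi_1 = 0, p_wi_2 = 0.7,
                     p_su_1 = 5.7, p_su_2 = 9.6)
wc <- wastage_params("constant", p_wi_1 = 0.5, p_su_1 = 8.5)
zg <- seq(200, 5800, by = 100)

test_that("discounted objective matches hand values", {
  expect_equal(npv_objective(c(100, 100), c(0, 0), r = 1), 150)
  expect_equal(npv_objective(100, 0, r = 0.37), 100)      # t = 0 undiscounted
  expect_equal(npv_objective(c(10, 20, 30), c(1, 2, 3), r = 0), 54)
  expect_error(npv_objective(1:3, 1:2, 0.05))
})

test_that("zero meat price makes husbandry unprofitable and feed pointless", {
  sw <- steady_state_sweep(wc, econ_params(price = 0),
                           z_grid = seq(500, 5500, by = 500))
  ok <- sw$curve$feasible
  expect_true(all(sw$curve$income[ok] <= 0))
  expect_lte(sw$optimum$income, 0)
  # with worthless meat the optimiser never buys feed where the pasture
  # alone sustains the herd, in particular at the optimum
  expect_equal(sw$optimum$v, 0)
})

test_that("steady states satisfy both fixed points", {
  ds <- load_districts(table1_path())
  sol <- district_optimum(ds$districts[ds$districts$district_id == "HD7", ],
                          wl, z_grid = seq(100, 2500, by = 50))
  expect_true(sol$feasible)
  expect_lt(sol$residuals[["lichen"]], 1e-6)
  expect_lt(sol$residuals[["population"]], 1e-6)
  expect_s3_class(sol$population, "population_state")
})

test_that("raising constant wastage lowers income and herd, not the optimum biomass", {
  s3 <- steady_state_sweep(wastage_params("constant", 0.3, p_su_1 = 8.5),
                           z_grid = zg)
  s5 <- steady_state_sweep(wastage_params("constant", 0.5, p_su_1 = 8.5),
                           z_grid = zg)
  expect_equal(s5$optimum$z, s3$optimum$z)
  expect_lt(s5$optimum$income, s3$optimum$income)
  expect_lt(s5$optimum$herd, s3$optimum$herd)
})

test_that("linear wastage moves the optimal biomass strictly below constant", {
  sc <- steady_state_sweep(wc, z_grid = zg)
  sl <- steady_state_sweep(wl, z_grid = zg)
  expect_lt(sl$optimum$z, sc$optimum$z)
  # and below the biomass maximising annual lichen growth (logistic: K/2)
  expect_lt(sl$optimum$z, grazing_config()$K / 2)
})

test_that("income vanishes as the steady-state biomass collapses", {
  sw <- steady_state_sweep(wl, allow_feeding = FALSE,
                           z_grid = c(5, 10, 25, 50, seq(100, 5500, 200)))
  ok <- sw$curve$feasible
  low <- sw$curve$z <= 50
  peak <- max(sw$curve$income[ok])
  expect_true(all(!ok[low] | sw$curve$income[low] < 0.1 * peak))
})

test_that("free feed makes the feeding-intensive regime optimal at any interest", {
  ff <- feeding_frontier(wl, r_grid = c(0, 0.05),
                         feed_cost_grid = c(1e-6, 0.2),
                         z_grid = seq(400, 5200, by = 400))
  expect_true(all(ff$classification[, 1]))
  # classification is binary and exhaustive
  expect_true(all(ff$classification %in% c(TRUE, FALSE)))
})

test_that("the feeding frontier rises with the interest rate", {
  fg <- seq(0.01, 0.09, by = 0.01)
  ff <- feeding_frontier(wc, r_grid = c(0, 0.04, 0.08), feed_cost_grid = fg,
                         z_grid = seq(400, 5200, by = 200))
  f <- ff$frontier$max_feed_cost
  f[is.na(f)] <- 0
  expect_true(all(diff(f) >= 0))
  expect_gt(f[3], f[1])
})

test_that("district optima respond sensibly to pasture size and prices", {
  ds <- tiny_ds(3, seed = 70)
  rec <- ds$districts[1, ]
  zgq <- seq(100, 2500, by = 100)
  sol <- district_optimum(rec, wl, z_grid = zgq)
  tiny <- rec; tiny$area_lichen <- rec$area_lichen / 100
  sol_tiny <- district_optimum(tiny, wl, z_grid = zgq)
  expect_lt(sol_tiny$herd, sol$herd / 50)
  rich <- district_optimum(rec, wl, econ_params(price = 16, interest = 0.02),
                           z_grid = zgq)
  expect_gte(rich$herd, sol$herd)
})

test_that("comparison with data counts districts above their optimum", {
  ds <- tiny_ds(3, seed = 70)
  sols <- lapply(seq_len(3), function(i)
    district_optimum(ds$districts[i, ], wl, z_grid = seq(100, 2500, by = 100)))
  cmp <- compare_to_data(sols, ds)
  expect_equal(nrow(cmp$table), 3)
  expect_true(cmp$n_herd_above %in% 0:3)
  expect_true(cmp$n_biomass_above %in% 0:3)
  expect_true(all(c("herd_observed", "herd_optimal") %in% names(cmp$table)))
})
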