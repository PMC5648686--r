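test_that("the packaged district table loads and reproduces the printed values", {
  ds <- load_districts(table1_path())
  d <- ds$districts
  expect_equal(nrow(d), 20)
  hd1 <- d[d$district_id == "HD1", ]
  expect_identical(hd1$rotation, FALSE)
  expect_equal(hd1$area_lichen, 78780)
  expect_equal(hd1$z_1995, 33)
  expect_equal(hd1$z_2008, 129)
  expect_equal(hd1$growth_rel, 0.49)
  expect_equal(d$infra_pct[d$district_id == "HD13"], 27.2)
  expect_equal(d$infra_pct[d$district_id == "HD9"], 2.5)
  expect_equal(sum(d$rotation), 8)
  expect_true(all(d$arboreal_avail %in% c(6, 9, 12)))
})

test_that("invalid district tables are rejected with the offending row identified", {
  d <- read.csv(table1_path())
  expect_error(district_set(d[0, ]), "no districts")
  bad <- d; bad$area_lichen[3] <- -5
  expect_error(district_set(bad), "row 3")
  expect_error(district_set(d[, -4]), "missing column")
  bad <- d; bad$z_1995[2] <- "abc"
  expect_error(district_set(bad), "non-numeric")
  bad <- d; bad$growth_rel[1] <- 1.4
  expect_error(district_set(bad), "growth_rel")
})

test_that("write/load round trip reproduces the table", {
  ds <- tiny_ds(4)
  tp <- tempfile(fileext = ".csv"); hp <- tempfile(fileext = ".csv")
  write_districts(ds, tp, hp)
  ds2 <- load_districts(tp, hp)
  expect_equal(ds2$districts, ds$districts, tolerance = 1e-12)
  expect_equal(ds2$herd, ds$herd, tolerance = 1e-12)
  # and the shipped fixture survives a round trip byte-for-byte in content
  ds3 <- load_districts(table1_path())
  tp3 <- tempfile(fileext = ".csv")
  write_districts(ds3, tp3)
  expect_equal(load_districts(tp3)$districts, ds3$districts)
})

test_that("minimum uncounted reindeer follows the census balance", {
  expect_equal(min_uncounted(1000, 950, 30, 30), 10)
  expect_equal(min_uncounted(1000, 900, 50, 50), 0)
  expect_equal(min_uncounted(0, 100, 0, 0), 100)
  expect_error(min_uncounted(-1, 0, 0, 0))
})

test_that("minimum uncounted is monotone in its arguments", {
  set.seed(1)
  for (k in 1:50) {
    a <- runif(1, 0, 2000); cnt <- runif(1, 0, 2000)
    sl <- runif(1, 0, 300); dt <- runif(1, 0, 200)
    base <- min_uncounted(a, cnt, sl, dt)
    expect_gte(min_uncounted(a, cnt + 10, sl, dt), base)
    expect_gte(min_uncounted(a, cnt, sl, dt + 10), base)
    expect_lte(min_uncounted(a + 10, cnt, sl, dt), base)
  }
})

test_that("herd correction applies the 10% floor and data-implied shares", {
  h <- flat_herd()
  hs <- corrected_herd(h)
  # flat series: implied share ~ 0 (slaughter+deaths exceed balance), so the
  # default 10% applies everywhere and corrected = raw / 0.9
  expect_true(all(abs(hs$uncounted_share - 0.10) < 1e-12))
  raw_total <- h$calves_alive + h$females_alive + h$males_alive
  expect_equal(hs$total, raw_total / 0.9, tolerance = 1e-12)
  expect_true(all(hs$total / raw_total >= 1 / 0.9 - 1e-12))
  # predation inflation: reported 10 -> 15 effective among winter deaths
  expect_equal(hs$winter_deaths[1], 5 + 1.5 * 10)
})

test_that("a data-implied share above 10% overrides the floor", {
  h <- flat_herd()
  # year 2000: census missed a large part of the herd, which reappears in
  # the 2001 counts; the balance then implies a share above the floor
  i <- which(h$year == 2000)
  h[i, c("calves_alive", "females_alive", "males_alive")] <-
    c(250, 550, 200) * 0.7
  hs <- corrected_herd(h)
  expect_gt(hs$uncounted_share[i], 0.10)
  expect_true(all(abs(hs$uncounted_share[-i] - 0.10) < 1e-12))
})

test_that("reindeer-days follow season lengths with mid-winter attrition", {
  h <- flat_herd()
  hs <- corrected_herd(h)
  sched <- season_schedule()
  tot <- hs$total[1]; dth <- hs$winter_deaths[1]
  expect_equal(hs$rd_wi[1], 180 * (tot - dth / 2))
  expect_equal(hs$rd_sp[1], 60 * (tot - dth))
  expect_equal(hs$rd_su[1], 95 * (tot - dth))
  expect_equal(hs$rd_au[1], 30 * (tot - dth))
  expect_true(all(hs[, c("rd_wi", "rd_sp", "rd_su", "rd_au")] >= 0))
})
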