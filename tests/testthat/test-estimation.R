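test_that("modeling efficiency matches its definition and edge cases", {
  obs <- c(100, 200, 300)
  expect_equal(modeling_efficiency(obs, c(110, 190, 310)), 0.985)
  expect_equal(modeling_efficiency(obs, obs), 1)
  expect_equal(modeling_efficiency(obs, rep(mean(obs), 3)), 0)
  expect_error(modeling_efficiency(c(5, 5, 5), c(1, 2, 3)), "identical")
  expect_error(modeling_efficiency(1:3, 1:4))
  # worse than the mean predictor goes negative
  expect_lt(modeling_efficiency(obs, c(300, 100, 200)), 0)
})

test_that("modeling efficiency is invariant under common affine rescaling", {
  set.seed(2)
  for (k in 1:20) {
    o <- rnorm(15, 50, 20); p <- o + rnorm(15, 0, 10)
    a <- runif(1, 0.1, 5); b <- runif(1, -100, 100)
    expect_equal(modeling_efficiency(a * o + b, a * p + b),
                 modeling_efficiency(o, p), tolerance = 1e-9)
  }
})

test_that("pearson correlation matches hand values", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "variance")
  expect_error(pearson_r(1:2, 1:2))
})

test_that("the constant form ties the two anchors exactly", {
  ds <- tiny_ds(6, seed = 31, noise_sd = 0.05)
  est <- estimate_wastage(ds, "constant",
                          control = wastage_control(n_starts = 2, maxit = 150))
  expect_identical(est$params$p[["p_wi_1"]], est$params$p[["p_wi_2"]])
  expect_identical(est$params$p[["p_su_1"]], est$params$p[["p_su_2"]])
  expect_true(all(est$params$p >= 0))
})

test_that("zero-noise estimation recovers the generating parameters", {
  ds <- tiny_ds(10, seed = 5, noise_sd = 0)
  truth <- attr(ds, "truth")$params$p
  est <- estimate_wastage(ds, "linear")
  denom <- c(0.35, 0.35, 7.65, 7.65)  # seasonal mean levels for zero truths
  relerr <- abs(est$params$p - truth) / ifelse(truth > 0, truth, denom)
  expect_true(all(relerr < 0.05))
  expect_gt(est$EF, 0.999)
})

test_that("the optimiser is not beaten by a large brute-force grid", {
  ds <- tiny_ds(8, seed = 13, noise_sd = 0.05)
  inputs <- reinpast:::.sim_inputs(ds)
  est <- estimate_wastage(ds, "linear", inputs = inputs)
  set.seed(99)
  grid <- cbind(runif(1e4, 0, 2), runif(1e4, 0, 2),
                runif(1e4, 0, 14), runif(1e4, 0, 14))
  obs <- ds$districts$z_2008
  sst <- sum((obs - mean(obs))^2)
  ef_grid <- apply(grid, 1, function(p)
    1 - sum((obs - reinpast:::.predict_z2008(inputs, p))^2) / sst)
  expect_gte(est$EF, max(ef_grid) - 1e-6)
})

test_that("cross-validation holds each district out and aggregates honestly", {
  ds <- tiny_ds(6, seed = 8, noise_sd = 0.03)
  fit <- fit_wastage(ds, "linear",
                     control = wastage_control(n_starts = 3, maxit = 200))
  expect_s3_class(fit, "wastage_fit")
  expect_equal(nrow(fit$folds), 6)
  expect_lte(fit$EF, 1)
  expect_equal(coef(fit), colMeans(fit$folds))
  expect_equal(residuals(fit),
               fit$predictions$observed - fit$predictions$predicted)
  # removing a district changes the training set: fold estimates are not all
  # identical to the full-data estimate
  expect_false(all(apply(fit$folds, 1, function(p)
    isTRUE(all.equal(p, fit$full$params$p)))))
  # predictions from the mean coefficients track the fold predictions
  pr <- predict(fit, ds)
  expect_equal(length(pr), 6)
  expect_true(all(is.finite(pr)))
  expect_output(print(fit), "Modeling efficiency")
  expect_output(print(summary(fit)), "Pearson")
})

test_that("the neutral ablation reproduces the full model bit for bit", {
  ds <- tiny_ds(5, seed = 21, noise_sd = 0.03)
  ctrl <- wastage_control(n_starts = 2, maxit = 120)
  full <- fit_wastage(ds, "linear", control = ctrl)
  neutral <- run_ablation(ds, ablation_spec(), form = "linear", control = ctrl)
  expect_identical(neutral$EF, full$EF)
  expect_identical(neutral$folds, full$folds)
  expect_error(ablation_spec(no_rotation = TRUE, rotation_everywhere = TRUE),
               "exclusive")
})

test_that("ablation toggles change the simulation inputs as intended", {
  ds <- tiny_ds(5, seed = 21)
  base <- reinpast:::.sim_inputs(ds)
  nf <- reinpast:::.sim_inputs(ds, ablation = ablation_spec(no_feeding = TRUE))
  expect_true(all(nf$dist[, "feeding"] == 0))
  na <- reinpast:::.sim_inputs(ds, ablation = ablation_spec(no_arboreal = TRUE))
  expect_true(all(na$dist[, "arb_pool"] == 0))
  og <- reinpast:::.sim_inputs(ds,
                               ablation = ablation_spec(one_growth_rate = TRUE))
  expect_true(all(og$dist[, "g"] == 1))
  ni <- reinpast:::.sim_inputs(ds, ablation = ablation_spec(infra_scale = 0))
  expect_true(all(ni$dist[, "infra_w"] == 0))
  half <- reinpast:::.sim_inputs(ds, ablation = ablation_spec(infra_scale = 0.5))
  expect_equal(half$dist[, "infra_w"], base$dist[, "infra_w"] / 2)
  rot <- reinpast:::.sim_inputs(ds,
                                ablation = ablation_spec(rotation_everywhere = TRUE))
  expect_true(all(rot$dist[, "rotation"] == 1))
})
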