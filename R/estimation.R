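#' Modeling efficiency (Nash-Sutcliffe type)
#'
#' `EF = 1 - SSE/SST`, the fraction of observed variance explained by the
#' model predictions: 1 for a perfect fit, 0 for the mean-of-observations
#' predictor, negative when the model does worse than the mean.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return the modeling efficiency (always <= 1).
#' @examples
#' modeling_efficiency(c(100, 200, 300), c(110, 190, 310))  # 0.985
#' @export
modeling_efficiency <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2,
            all(is.finite(observed)), all(is.finite(predicted)))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are all identical; EF undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the precondition checks used
#' throughout the validation outputs.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3) with
#'   nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("zero variance; correlation undefined")
  stats::cor(observed, predicted)
}

#' Ablation specification
#'
#' Switches individual model extensions off (or rescales them) to measure
#' their contribution to the validation fit. Used by [run_ablation()].
#'
#' @param no_feeding drop supplementary feeding.
#' @param no_arboreal drop arboreal lichen pastures.
#' @param one_growth_rate set the relative growth rate to 1 (mature/old pine)
#'   in every district.
#' @param no_rotation treat every district as grazed year-round.
#' @param rotation_everywhere treat every district as rotating (exclusive
#'   with `no_rotation`).
#' @param infra_scale multiplier on infrastructure-induced wastage (0 removes
#'   it; 0.5 and 1.5 are the sensitivity variants).
#' @param nickel_scale multiplier on the heavy-metal growth reduction.
#' @param wastage_form optional override of the wastage form for the re-fit.
#' @return an object of class `ablation_spec`.
#' @export
ablation_spec <- function(no_feeding = FALSE, no_arboreal = FALSE,
                          one_growth_rate = FALSE, no_rotation = FALSE,
                          rotation_everywhere = FALSE, infra_scale = 1,
                          nickel_scale = 1, wastage_form = NULL) {
  if (no_rotation && rotation_everywhere)
    stop("no_rotation and rotation_everywhere are mutually exclusive")
  stopifnot(infra_scale >= 0, nickel_scale >= 0)
  structure(list(no_feeding = no_feeding, no_arboreal = no_arboreal,
                 one_growth_rate = one_growth_rate, no_rotation = no_rotation,
                 rotation_everywhere = rotation_everywhere,
                 infra_scale = infra_scale, nickel_scale = nickel_scale,
                 wastage_form = wastage_form), class = "ablation_spec")
}

# Precompute the matrices the C++ kernel consumes: one row per district with
# static parameters (ablation toggles already applied) and the corrected
# reindeer-days per year x season.
.sim_inputs <- function(ds, schedule = season_schedule(),
                        config = grazing_config(),
                        ablation = ablation_spec()) {
  stopifnot(inherits(ds, "district_set"))
  d <- ds$districts
  n <- nrow(d)
  feeding <- if (ablation$no_feeding) rep(0, n) else d$feeding
  pool <- if (ablation$no_arboreal) rep(0, n)
          else d$arboreal_avail * d$area_arboreal
  g <- if (ablation$one_growth_rate) rep(1, n) else d$growth_rel
  rotation <- d$rotation
  if (ablation$no_rotation) rotation <- rep(FALSE, n)
  if (ablation$rotation_everywhere) rotation <- rep(TRUE, n)
  hm <- pmax(0, 1 - ablation$nickel_scale * d$heavy_metal_pct / 100)
  infra_w <- infra_wastage(d$infra_pct) * ablation$infra_scale

  dist <- cbind(z0 = d$z_1995, area = d$area_lichen, arb_pool = pool,
                feeding = feeding, g = g, hm = hm, infra_w = infra_w,
                rotation = as.numeric(rotation))
  rd_list <- lapply(d$district_id, function(id) {
    hs <- corrected_herd(ds, id, schedule = schedule)
    as.vector(t(as.matrix(hs[, c("rd_wi", "rd_sp", "rd_su", "rd_au")])))
  })
  nyears <- length(rd_list[[1]]) / 4
  if (any(vapply(rd_list, length, 1L) != nyears * 4))
    stop("herd series lengths differ between districts")
  rd <- do.call(rbind, rd_list)
  cfg <- c(config$demand, config$z_half, config$feed_sub, config$arboreal_cap,
           config$K, config$r0, as.numeric(config$growth == "gompertz"),
           as.numeric(config$infra_seasons == "winter"),
           schedule$days[["wi"]],
           schedule$spring_exposure_days / schedule$days[["sp"]])
  list(dist = dist, rd = rd, cfg = unname(cfg), obs = d$z_2008,
       z1995 = d$z_1995, ids = d$district_id, n = n)
}

# z_2008 predictions from precomputed inputs for a parameter vector
# (p_wi_1, p_wi_2, p_su_1, p_su_2); rows optionally subset districts.
.predict_z2008 <- function(inputs, pvec, rows = NULL) {
  dist <- inputs$dist; rd <- inputs$rd
  if (!is.null(rows)) {
    dist <- dist[rows, , drop = FALSE]
    rd <- rd[rows, , drop = FALSE]
  }
  traj <- cpp_simulate_districts(dist, rd, pvec, inputs$cfg)
  traj[, ncol(traj)]
}

#' Optimiser control for wastage estimation
#'
#' @param n_starts number of simplex starts taken from the best coarse-grid
#'   points (constant form uses at most `n_starts`).
#' @param maxit maximum Nelder-Mead iterations per start.
#' @param reltol relative convergence tolerance on the objective.
#' @param grid optional data frame of explicit grid-seed points (columns
#'   `p_wi_1`, `p_wi_2`, `p_su_1`, `p_su_2`).
#' @return a list of class `wastage_control`.
#' @export
wastage_control <- function(n_starts = 8, maxit = 400, reltol = 1e-10,
                            grid = NULL) {
  structure(list(n_starts = n_starts, maxit = maxit, reltol = reltol,
                 grid = grid), class = "wastage_control")
}

.default_grid <- function(form) {
  if (form == "constant") {
    g <- expand.grid(wi = seq(0, 1.5, by = 0.25), su = seq(1, 13, by = 1))
    data.frame(p_wi_1 = g$wi, p_wi_2 = g$wi, p_su_1 = g$su, p_su_2 = g$su)
  } else {
    expand.grid(p_wi_1 = c(0, 0.4, 1), p_wi_2 = c(0, 0.7, 1.5),
                p_su_1 = c(2, 5, 8), p_su_2 = c(4, 8, 12))
  }
}

#' Estimate wastage parameters by maximising modeling efficiency
#'
#' Finds the seasonal wastage-to-intake multipliers that maximise the
#' modeling efficiency of predicted versus observed 2008 lichen biomasses
#' over the supplied districts. Deterministic: a coarse grid seeds a fixed
#' number of Nelder-Mead simplex starts (parameters kept non-negative via a
#' square transform); the best start wins, ties broken by first found. The
#' returned EF is never below any grid point's EF.
#'
#' @param ds a [district_set] with herd series.
#' @param form `"linear"` or `"constant"`.
#' @param control a [wastage_control()].
#' @param schedule,config forward-model settings.
#' @param ablation an [ablation_spec()]; the default is the full model.
#' @param inputs precomputed `.sim_inputs` (internal use).
#' @param rows optional district subset (internal use; cross-validation folds).
#' @return list with `params` (a [wastage_params]), `EF` (achieved in-sample
#'   modeling efficiency), and `evals` (objective evaluation count).
#' @export
estimate_wastage <- function(ds, form = c("linear", "constant"),
                             control = wastage_control(),
                             schedule = season_schedule(),
                             config = grazing_config(),
                             ablation = ablation_spec(),
                             inputs = NULL, rows = NULL) {
  form <- match.arg(form)
  if (is.null(inputs)) inputs <- .sim_inputs(ds, schedule, config, ablation)
  idx <- if (is.null(rows)) seq_len(inputs$n) else rows
  if (length(idx) < 2) stop("need at least 2 districts to estimate")
  obs <- inputs$obs[idx]
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("observed z_2008 identical across districts")
  evals <- 0L

  ef_of <- function(pvec) {
    evals <<- evals + 1L
    pred <- .predict_z2008(inputs, pvec, rows = idx)
    1 - sum((obs - pred)^2) / sst
  }
  # free parameters: constant form ties p_e_1 = p_e_2
  expand <- if (form == "constant") function(th) {
    p <- th^2; c(p[1], p[1], p[2], p[2])
  } else function(th) th^2

  grid <- if (!is.null(control$grid)) control$grid else .default_grid(form)
  grid_ef <- apply(as.matrix(grid[, c("p_wi_1", "p_wi_2", "p_su_1", "p_su_2")]),
                   1L, ef_of)
  ord <- order(-grid_ef)
  n_st <- min(control$n_starts, length(ord))
  best <- list(ef = grid_ef[ord[1]],
               p = as.numeric(grid[ord[1], c("p_wi_1", "p_wi_2",
                                             "p_su_1", "p_su_2")]))
  for (s in seq_len(n_st)) {
    p0 <- as.numeric(grid[ord[s], c("p_wi_1", "p_wi_2", "p_su_1", "p_su_2")])
    th0 <- if (form == "constant") sqrt(p0[c(1, 3)]) else sqrt(p0)
    opt <- stats::optim(th0, function(th) -ef_of(expand(th)),
                        method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    if (-opt$value > best$ef) best <- list(ef = -opt$value, p = expand(opt$par))
  }
  params <- wastage_params(form, p_wi_1 = best$p[1], p_wi_2 = best$p[2],
                           p_su_1 = best$p[3], p_su_2 = best$p[4])
  list(params = params, EF = best$ef, evals = evals)
}

#' Fit seasonal lichen wastage by leave-one-out cross-validation
#'
#' The package's central estimator. Each herding district is held out in
#' turn; the wastage multipliers are estimated on the remaining districts by
#' maximising modeling efficiency, and the held-out district's 2008 lichen
#' biomass is predicted with those parameters. The cross-validated EF and
#' Pearson correlations (on 2008 levels and on the 1995-2008 change)
#' summarise how well the grazing/trampling model transfers to unseen
#' districts; the reported coefficients are the arithmetic mean of the fold
#' estimates.
#'
#' @param ds a [district_set] with herd series.
#' @param form `"linear"` or `"constant"` wastage (see [wastage_params()]).
#' @param cv if `FALSE`, skip cross-validation and fit once on all districts
#'   (predictions are then in-sample).
#' @param control a [wastage_control()].
#' @param schedule,config forward-model settings.
#' @param ablation an [ablation_spec()]; defaults to the full model.
#' @return an object of class `wastage_fit` with components `coefficients`
#'   (mean fold parameters), `folds` (per-fold parameter matrix),
#'   `predictions` (district, observed and predicted z_2008, z_1995), `EF`,
#'   `r_levels`, `r_changes`, `EF_folds`, `form`, and the full-data estimate
#'   under `full`.
#' @seealso [estimate_wastage()], [run_ablation()], [modeling_efficiency()]
#' @examples
#' \donttest{
#' ds <- generate_district_set(synthetic_config(n_districts = 8, seed = 1))
#' fit <- fit_wastage(ds, form = "linear")
#' summary(fit)
#' }
#' @export
fit_wastage <- function(ds, form = c("linear", "constant"), cv = TRUE,
                        control = wastage_control(),
                        schedule = season_schedule(),
                        config = grazing_config(),
                        ablation = ablation_spec()) {
  form <- match.arg(form)
  if (!is.null(ablation$wastage_form)) form <- ablation$wastage_form
  inputs <- .sim_inputs(ds, schedule, config, ablation)
  n <- inputs$n
  full <- estimate_wastage(ds, form, control, inputs = inputs)
  if (cv) {
    if (n < 3) stop("need at least 3 districts for cross-validation")
    folds <- matrix(NA_real_, n, 4,
                    dimnames = list(inputs$ids,
                                    c("p_wi_1", "p_wi_2", "p_su_1", "p_su_2")))
    ef_folds <- numeric(n)
    pred <- numeric(n)
    for (i in seq_len(n)) {
      est <- estimate_wastage(ds, form, control, inputs = inputs,
                              rows = setdiff(seq_len(n), i))
      folds[i, ] <- est$params$p
      ef_folds[i] <- est$EF
      pred[i] <- .predict_z2008(inputs, est$params$p, rows = i)
    }
  } else {
    folds <- matrix(full$params$p, 1, 4,
                    dimnames = list(NULL,
                                    c("p_wi_1", "p_wi_2", "p_su_1", "p_su_2")))
    ef_folds <- full$EF
    pred <- .predict_z2008(inputs, full$params$p)
  }
  obs <- inputs$obs
  co <- colMeans(folds)
  fit <- structure(list(
    coefficients = co,
    form = form,
    folds = folds,
    EF_folds = ef_folds,
    predictions = data.frame(district_id = inputs$ids, z_1995 = inputs$z1995,
                             observed = obs, predicted = pred),
    EF = modeling_efficiency(obs, pred),
    r_levels = pearson_r(obs, pred),
    r_changes = pearson_r(obs - inputs$z1995, pred - inputs$z1995),
    cv = cv, n = n, full = full, ablation = ablation,
    schedule = schedule, config = config, control = control,
    call = match.call()), class = "wastage_fit")
  fit
}

#' @export
print.wastage_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Lichen wastage fit (%s form), %d districts%s\n", x$form, x$n,
              if (x$cv) ", leave-one-out CV" else ""))
  cat("Mean wastage multipliers (z = 0 / 1000 kg/ha):\n")
  cat(sprintf("  winter %.3g / %.3g   summer %.3g / %.3g\n",
              x$coefficients[1], x$coefficients[2],
              x$coefficients[3], x$coefficients[4]))
  cat(sprintf("Modeling efficiency (held-out): %.*g\n", digits, x$EF))
  invisible(x)
}

#' @export
summary.wastage_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.wastage_fit")
}

#' @export
print.summary.wastage_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("Pearson r: %.3f (2008 levels), %.3f (1995-2008 change)\n",
              f$r_levels, f$r_changes))
  if (f$cv) {
    rng <- apply(f$folds, 2, range)
    cat("Fold estimate ranges:\n")
    for (j in seq_len(4))
      cat(sprintf("  %s: %.3g - %.3g\n", colnames(f$folds)[j],
                  rng[1, j], rng[2, j]))
  }
  cat("Observed vs predicted z_2008 (kg/ha):\n")
  print(format(x$fit$predictions, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.wastage_fit <- function(object, ...) object$coefficients

#' @export
fitted.wastage_fit <- function(object, ...) object$predictions$predicted

#' @export
residuals.wastage_fit <- function(object, ...) {
  object$predictions$observed - object$predictions$predicted
}

#' Predict 2008 lichen biomass for districts
#'
#' Runs the forward pasture model with the fit's mean wastage multipliers.
#'
#' @param object a `wastage_fit`.
#' @param newdata a [district_set] with herd series; defaults to refitting
#'   data is not stored, so `newdata` is required.
#' @param ... unused.
#' @return numeric vector of predicted z_2008 (kg/ha), one per district.
#' @export
predict.wastage_fit <- function(object, newdata, ...) {
  inputs <- .sim_inputs(newdata, object$schedule, object$config,
                        object$ablation)
  .predict_z2008(inputs, unname(object$coefficients))
}

#' Observed-versus-predicted plot
#'
#' @param x a `wastage_fit`.
#' @param change plot the 1995-2008 biomass change instead of 2008 levels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wastage_fit <- function(x, change = FALSE, ...) {
  p <- x$predictions
  if (change) {
    ox <- p$observed - p$z_1995; oy <- p$predicted - p$z_1995
    lab <- "change in lichen biomass 1995-2008 (kg/ha)"
  } else {
    ox <- p$observed; oy <- p$predicted
    lab <- "lichen biomass 2008 (kg/ha)"
  }
  graphics::plot(ox, oy, xlab = paste("observed", lab),
                 ylab = paste("predicted", lab), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Re-fit the model with an extension switched off
#'
#' Applies an [ablation_spec()] toggle (drop feeding, arboreal lichens,
#' growth-rate variation, rotation, infrastructure or heavy-metal effects, or
#' rescale the latter two), re-runs the full leave-one-out estimation with
#' wastage re-optimised, and reports the resulting modeling efficiency.
#'
#' @param ds a [district_set] with herd series.
#' @param spec an [ablation_spec()].
#' @param form wastage form for the re-fit (overridden by
#'   `spec$wastage_form` when set).
#' @param ... passed to [fit_wastage()].
#' @return the ablated `wastage_fit`; its `$EF` is the cross-validated
#'   modeling efficiency of the reduced model.
#' @export
run_ablation <- function(ds, spec, form = "linear", ...) {
  stopifnot(inherits(spec, "ablation_spec"))
  fit_wastage(ds, form = form, ablation = spec, ...)
}
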