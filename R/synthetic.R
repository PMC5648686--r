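#' Configuration for synthetic herding-district data
#'
#' Describes the distributions from which synthetic districts and herd
#' series are drawn. Defaults emulate the observed range of the 20
#' northernmost Finnish districts: pasture areas, arboreal availability
#' classes, growth rates, heavy-metal bands and infrastructure shares span
#' the fixture table; initial lichen biomasses cover the observed 65-1800
#' kg/ha span; herd trajectories follow an AR(1) around a district mean
#' density; a fixed 10% of the herd goes uncounted (the `"variable"` pattern
#' adds years with larger uncounted shares followed by complete counts so
#' the bookkeeping reconstruction is exercised); reported predation is the
#' true predation deaths divided by 1.5.
#'
#' @param n_districts number of districts.
#' @param seed integer seed fixing all draws.
#' @param true_params generating [wastage_params()].
#' @param noise_sd relative observation noise on the 2008 biomass.
#' @param years herd-series years (drivers; the biomass endpoint is the year
#'   after the last).
#' @param area_range,arboreal_area_range ranges (ha), sampled log-uniformly
#'   for the lichen area.
#' @param z1995_range initial biomass range (kg/ha), log-uniform.
#' @param g_range relative growth-rate range.
#' @param infra_range infrastructure disturbance range (%).
#' @param rotation_prob probability a district uses pasture rotation.
#' @param hm_levels,hm_probs heavy-metal growth-reduction levels (%) and
#'   their sampling weights.
#' @param density_range mean herd density range (head per ha of lichen
#'   pasture).
#' @param herd_ar,herd_cv AR(1) coefficient and coefficient of variation of
#'   the herd trajectory.
#' @param uncounted `"fixed"` (10% every year) or `"variable"`.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_districts = 20, seed = 1,
                             true_params = wastage_params(
                               "linear", p_wi_1 = 0, p_wi_2 = 0.7,
                               p_su_1 = 5.7, p_su_2 = 9.6),
                             noise_sd = 0.05, years = 1995:2007,
                             area_range = c(10000, 130000),
                             arboreal_area_range = c(2000, 80000),
                             z1995_range = c(65, 1800),
                             g_range = c(0.49, 0.91),
                             infra_range = c(2.5, 27.2),
                             rotation_prob = 0.4,
                             hm_levels = c(0, 20, 40, 60),
                             hm_probs = c(11, 6, 2, 1) / 20,
                             density_range = c(0.06, 0.20),
                             herd_ar = 0.6, herd_cv = 0.10,
                             uncounted = c("fixed", "variable")) {
  uncounted <- match.arg(uncounted)
  stopifnot(n_districts >= 2, noise_sd >= 0, length(years) >= 2,
            rotation_prob >= 0, rotation_prob <= 1,
            all(hm_probs >= 0), herd_cv >= 0, abs(herd_ar) < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a synthetic district set with known ground truth
#'
#' Draws district parameters, simulates herd series with an uncounted
#' fraction and under-reported predation, drives the forward pasture model
#' with the *same* correction pipeline the estimator uses, and stores the
#' resulting 2008 biomass plus relative observation noise. The generating
#' truth is attached as attribute `"truth"` (true parameters, noise-free
#' biomasses, true uncounted shares).
#'
#' @param config a [synthetic_config()].
#' @param schedule,grazing forward-model settings (must match the settings
#'   later used for estimation).
#' @return a [district_set] with herd series and a `"truth"` attribute.
#' @export
generate_district_set <- function(config = synthetic_config(),
                                  schedule = season_schedule(),
                                  grazing = grazing_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_districts
  yrs <- config$years
  ny <- length(yrs)

  d <- data.frame(
    district_id = sprintf("SD%02d", seq_len(n)),
    rotation = stats::runif(n) < config$rotation_prob,
    feeding = sample(c(12, 37, 75, 125, 200), n, replace = TRUE,
                     prob = c(0.45, 0.15, 0.2, 0.1, 0.1)),
    area_lichen = round(.runif_log(n, config$area_range)),
    area_arboreal = round(stats::runif(n, config$arboreal_area_range[1],
                                       config$arboreal_area_range[2])),
    arboreal_avail = sample(c(6, 9, 12), n, replace = TRUE),
    z_1995 = round(.runif_log(n, config$z1995_range)),
    z_2008 = NA_real_,
    growth_rel = round(stats::runif(n, config$g_range[1], config$g_range[2]), 2),
    heavy_metal_pct = sample(config$hm_levels, n, replace = TRUE,
                             prob = config$hm_probs),
    infra_pct = round(stats::runif(n, config$infra_range[1],
                                   config$infra_range[2]), 1))

  shares <- matrix(0.10, n, ny)
  if (config$uncounted == "variable") {
    # occasional poorly-counted years (> 10%) followed by a complete count,
    # so the minimum-uncounted bookkeeping can recover the share exactly
    for (i in seq_len(n)) {
      k <- sample(2:(ny - 1), 1)
      shares[i, k] <- stats::runif(1, 0.12, 0.22)
      shares[i, k + 1] <- 0
    }
  }

  herd <- vector("list", n)
  true_n <- matrix(NA_real_, n, ny)
  for (i in seq_len(n)) {
    mean_n <- stats::runif(1, config$density_range[1],
                           config$density_range[2]) * d$area_lichen[i]
    x <- numeric(ny)
    x[1] <- stats::rnorm(1, 0, config$herd_cv)
    for (t in 2:ny)
      x[t] <- config$herd_ar * x[t - 1] +
        stats::rnorm(1, 0, config$herd_cv * sqrt(1 - config$herd_ar^2))
    N <- pmax(50, mean_n * (1 + x))
    true_n[i, ] <- N
    traffic <- round(0.005 * N)
    pred_true <- 0.02 * N
    pred_rep <- round(pred_true / 1.5)
    deaths <- traffic + 1.5 * pred_rep
    calves <- 0.25 * N
    females <- 0.55 * N
    males <- 0.20 * N
    # adults slaughtered in autumn t+1 close the balance: everything alive
    # after slaughter in t, minus winter deaths, is either counted as an
    # adult in t+1 or slaughtered then
    adults_next <- females + males
    ad_sl <- c(0, pmax(0, (N[-ny] - deaths[-ny]) - adults_next[-1]))
    s <- shares[i, ]
    herd[[i]] <- data.frame(
      district_id = d$district_id[i],
      year = yrs,
      calves_alive = round(calves * (1 - s)),
      females_alive = round(females * (1 - s)),
      males_alive = round(males * (1 - s)),
      calves_slaughtered = round(0.45 * calves),
      females_slaughtered = round(0.7 * ad_sl),
      males_slaughtered = round(0.3 * ad_sl),
      traffic_deaths = traffic,
      predation_reported = pred_rep)
  }
  herd <- do.call(rbind, herd)
  d$z_2008 <- d$z_1995                      # placeholder; replaced below
  ds <- district_set(d, herd)

  inputs <- .sim_inputs(ds, schedule, grazing)
  z_true <- .predict_z2008(inputs, config$true_params$p)
  eps <- stats::rnorm(n, 0, config$noise_sd)
  z_obs <- pmax(1, z_true * (1 + eps))
  ds$districts$z_2008 <- z_obs
  attr(ds, "truth") <- list(params = config$true_params, z_2008 = z_true,
                            uncounted_shares = shares, herd_true = true_n)
  ds
}

#' Parameter-recovery experiment
#'
#' Monte-Carlo check of the whole estimation pipeline: generates replicate
#' synthetic district sets under a known truth, runs the leave-one-out
#' wastage fit on each, and summarises per-parameter bias and the overall
#' cross-validated modeling efficiency. Relative bias is computed against
#' the true value, except for parameters whose truth is zero, where the
#' seasonal mean wastage level `(p_e_1 + p_e_2) / 2` is the denominator.
#'
#' @param config a [synthetic_config()]; replicate `i` uses
#'   `config$seed + i - 1`.
#' @param form wastage form to fit.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param control a [wastage_control()] for the per-fold optimiser.
#' @return object of class `recovery_report`: `$estimates` (replicates x 4),
#'   `$rel_bias`, `$EF` (per replicate), `$truth` and `$summary` (median
#'   relative bias and RMSE per parameter).
#' @export
recovery_experiment <- function(config = synthetic_config(), form = "linear",
                                n_replicates = 20,
                                control = wastage_control()) {
  truth <- config$true_params$p
  denom <- ifelse(truth > 0, truth,
                  rep(c(mean(truth[1:2]), mean(truth[3:4])), each = 2))
  est <- matrix(NA_real_, n_replicates, 4,
                dimnames = list(NULL, names(truth)))
  ef <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1
    ds <- generate_district_set(cfg)
    fit <- fit_wastage(ds, form = form, control = control)
    est[i, ] <- fit$coefficients
    ef[i] <- fit$EF
  }
  rel_bias <- sweep(sweep(est, 2, truth), 2, denom, "/")
  structure(list(
    estimates = est, rel_bias = rel_bias, EF = ef, truth = truth,
    form = form, n_replicates = n_replicates,
    summary = data.frame(
      parameter = names(truth), truth = unname(truth),
      median_estimate = apply(est, 2, stats::median),
      median_rel_bias = apply(rel_bias, 2, stats::median),
      rmse = sqrt(colMeans(sweep(est, 2, truth)^2)))),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery over %d replicates (%s form): median EF = %.3f\n",
              x$n_replicates, x$form, stats::median(x$EF)))
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}
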