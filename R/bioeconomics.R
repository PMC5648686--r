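#' Economic parameters
#'
#' Prices, costs and the discount rate of the husbandry economy. Values are
#' defaults exposed for calibration: meat price per kg, slaughter weights by
#' class, annual husbandry cost per head, feed cost per kg and the interest
#' rate.
#'
#' @param price meat price (currency/kg).
#' @param w_calf,w_female,w_male slaughter weights (kg/animal).
#' @param cost_per_head annual husbandry cost (currency/head/yr).
#' @param feed_cost supplementary feed cost (currency/kg).
#' @param interest annual interest (discount) rate.
#' @param max_density management cap on herd density (head per ha of lichen
#'   pasture); it bounds the herd only in the degenerate fully-fed regime
#'   where the lichen balance no longer does.
#' @return a list of class `econ_params`.
#' @export
econ_params <- function(price = 8, w_calf = 22, w_female = 35, w_male = 55,
                        cost_per_head = 40, feed_cost = 0.3, interest = 0,
                        max_density = 1) {
  stopifnot(price >= 0, w_calf >= 0, w_female >= 0, w_male >= 0,
            cost_per_head >= 0, feed_cost >= 0, interest >= 0,
            max_density > 0)
  structure(list(price = price, w_calf = w_calf, w_female = w_female,
                 w_male = w_male, cost_per_head = cost_per_head,
                 feed_cost = feed_cost, interest = interest,
                 max_density = max_density),
            class = "econ_params")
}

#' Net present value of a revenue/cost stream
#'
#' `J = sum_t (R_t - C_t) / (1 + r)^t`, the discounted objective of the
#' infinite-horizon management problem truncated to the supplied streams
#' (period 0 is undiscounted).
#'
#' @param revenue_stream,cost_stream equal-length numeric vectors.
#' @param r interest rate (>= 0).
#' @return the discounted sum.
#' @examples
#' npv_objective(c(100, 100), c(0, 0), r = 1)  # 150
#' @export
npv_objective <- function(revenue_stream, cost_stream, r) {
  stopifnot(length(revenue_stream) == length(cost_stream), r >= 0)
  t <- seq_along(revenue_stream) - 1
  sum((revenue_stream - cost_stream) / (1 + r)^t)
}

#' Site description for steady-state analysis
#'
#' The pasture-side constants of a (possibly fictional) herding district.
#'
#' @param area lichen-pasture area (ha).
#' @param rotation logical; closed seasonal pasture rotation.
#' @param g relative lichen growth rate (1 = mature/old pine).
#' @param hm heavy-metal growth multiplier (1 = none).
#' @param infra_pct infrastructure disturbance (% of area).
#' @param arboreal_pool arboreal lichen available per winter (kg).
#' @return a list of class `site_params`.
#' @export
site_params <- function(area = 10000, rotation = TRUE, g = 1, hm = 1,
                        infra_pct = 0, arboreal_pool = 0) {
  stopifnot(area > 0, g > 0, g <= 1, hm > 0, hm <= 1,
            infra_pct >= 0, infra_pct <= 100, arboreal_pool >= 0)
  structure(list(area = area, rotation = rotation, g = g, hm = hm,
                 infra_w = infra_wastage(infra_pct),
                 arboreal_pool = arboreal_pool), class = "site_params")
}

# Annual per-hectare lichen growth at biomass z for a site.
.site_growth <- function(z, site, grazing) {
  G <- if (grazing$growth == "gompertz")
    ifelse(z > 0, grazing$r0 * z * log(grazing$K / z), 0)
  else grazing$r0 * z * (1 - z / grazing$K)
  pmax(0, site$g * site$hm * G)
}

# Winter energy allocation per (adult-equivalent) head at biomass z with
# feed offered up to v (kg/head/winter) and arboreal availability ab_daily
# (kg/head/day). Optimal-foraging order: ground lichen through the
# functional response first, then arboreal lichen, then supplementary feed
# fills the residual deficit; only consumed feed is charged. Everything in
# lichen-equivalent kg/day.
.winter_percap <- function(z, v, ab_daily, grazing, demog, schedule) {
  days <- schedule$days[["wi"]]
  req <- demog$requirement_daily
  gi <- grazing$demand[["wi"]] * z / (z + grazing$z_half)
  ground <- pmin(gi, req)
  ab <- pmin(ab_daily, pmax(0, req - ground))
  fe <- pmin(v * grazing$feed_sub / days, pmax(0, req - ground - ab))
  deficit_rel <- (req - ground - ab - fe) / req
  list(ground_daily = ground, deficit_rel = deficit_rel, feed_daily = fe,
       arboreal_daily = ab,
       v_used = fe * days / max(grazing$feed_sub, 1e-12))
}

# Per-head annual lichen removal (kg) from the winter-range lichen area at
# biomass z, given the winter ground intake; non-winter seasons use the raw
# functional response, with rotation exposure and infrastructure wastage.
.percap_removal <- function(z, ground_wi_daily, site, wp, grazing, schedule) {
  days <- schedule$days
  expo <- if (site$rotation)
    c(wi = 1, sp = schedule$spring_exposure_days / days[["sp"]], su = 0, au = 0)
  else c(wi = 1, sp = 1, su = 1, au = 1)
  tot <- ground_wi_daily * (1 + relative_wastage(wp, z, "wi") + site$infra_w) *
    days[["wi"]] * expo[["wi"]]
  for (e in c("sp", "su", "au")) {
    gi <- grazing$demand[[e]] * z / (z + grazing$z_half)
    tot <- tot + gi * (1 + relative_wastage(wp, z, e) + site$infra_w) *
      days[[e]] * expo[[e]]
  }
  tot
}

# Best self-replacing harvest policy at given effective survival/calving:
# vectorised over the (q_f, q_m) grid. Returns the policy maximising meat
# value per head per year, or NULL when no policy sustains the herd.
.best_policy <- function(s_eff, c_eff, econ, demog, qf_grid, qm_grid) {
  qq <- expand.grid(q_f = qf_grid, q_m = qm_grid)
  r_f <- s_eff * (1 - qq$q_f)
  r_m <- s_eff * (1 - qq$q_m)
  amax_f <- demog$n_female - 1L
  amax_m <- demog$n_male - 1L
  pow <- function(r, ages) rowSums(outer(r, ages, "^"))
  phi_f <- pow(r_f, demog$fertile_min_age:amax_f)
  psi_m <- pow(r_m, demog$mature_min_age:amax_m)
  rho <- demog$sigma * psi_m / (demog$sigma * psi_m + phi_f)
  keep <- 2 / ((1 - demog$calf_mortality) * c_eff * phi_f * rho)
  ok <- is.finite(keep) & keep <= 1
  if (!any(ok)) return(NULL)
  q_c <- 1 - keep
  heads <- (1 - q_c) / 2 * (pow(r_f, 0:amax_f) + pow(r_m, 0:amax_m))
  hf <- (1 - q_c) / 2 * (pow(r_f, 0:(amax_f - 1)) * s_eff * qq$q_f +
                           r_f^amax_f * s_eff)
  hm <- (1 - q_c) / 2 * (pow(r_m, 0:(amax_m - 1)) * s_eff * qq$q_m +
                           r_m^amax_m * s_eff)
  meat_perB <- q_c * econ$w_calf + hf * econ$w_female + hm * econ$w_male
  value <- ifelse(ok, econ$price * meat_perB / heads, -Inf)
  i <- which.max(value)
  list(q_f = qq$q_f[i], q_m = qq$q_m[i], q_c = q_c[i], heads = heads[i],
       meat_perB = meat_perB[i], meat_value_percap = value[i])
}

# Inner steady-state problem at one biomass z: maximise per-head margin over
# harvest fractions (q_f, q_m) and feeding v; herd size follows from the
# lichen balance. Deterministic grid search (coordinate refinement is
# unnecessary: the margin surface is smooth and the grids are fine).
.steady_at_z <- function(z, site, wp, econ, grazing, demog, schedule,
                         allow_feeding, ab_daily = 0,
                         v_grid = NULL, qf_grid = seq(0, 0.45, by = 0.05),
                         qm_grid = seq(0, 0.8, by = 0.1)) {
  days_wi <- schedule$days[["wi"]]
  if (is.null(v_grid)) {
    v_full <- demog$requirement_daily * days_wi / grazing$feed_sub
    v_grid <- if (allow_feeding) seq(0, v_full, length.out = 19) else 0
  }
  growth_total <- site$area * .site_growth(z, site, grazing)
  best <- NULL
  for (v in v_grid) {
    wb <- .winter_percap(z, v, ab_daily, grazing, demog, schedule)
    cons <- .percap_removal(z, wb$ground_daily, site, wp, grazing, schedule)
    if (cons <= 0) next                      # lichen never binds: no interior
    N <- growth_total / cons
    d <- wb$deficit_rel
    s_eff <- demog$survival * max(0, 1 - demog$penalty_mortality * d)
    c_eff <- demog$calving * max(0, 1 - demog$penalty_calving * d)
    if (s_eff <= 0 || c_eff <= 0) next
    pol <- .best_policy(s_eff, c_eff, econ, demog, qf_grid, qm_grid)
    if (is.null(pol)) next
    percap <- pol$meat_value_percap - econ$cost_per_head -
      econ$feed_cost * wb$v_used
    income <- N * percap
    if (is.null(best) || income > best$income) {
      st <- .stationary_structure(s_eff, c_eff, pol$q_f, pol$q_m, demog)
      best <- list(income = income, N = N, v = wb$v_used, q_f = pol$q_f,
                   q_m = pol$q_m, q_c = pol$q_c, s_eff = s_eff,
                   c_eff = c_eff, deficit_rel = d, structure = st,
                   cons = cons, meat = pol$meat_perB * N / pol$heads)
    }
  }
  best
}

#' Steady-state net-income curve over lichen biomass
#'
#' For each target biomass `z*` on the grid, finds the largest sustainable
#' herd (annual lichen growth = annual removal), the self-replacing harvest
#' policy and the feeding intensity that maximise yearly net revenue, and
#' reports the income and herd-size curves and their optimum. With a
#' positive interest rate the selection criterion is the annual income less
#' the interest cost of the lichen capital held in the pasture.
#'
#' @param wastage_params a [wastage_params()].
#' @param econ an [econ_params()].
#' @param site a [site_params()]; the default is a fictional rotation
#'   district on mature/old pine with no arboreal lichen, infrastructure or
#'   heavy metals.
#' @param z_grid steady-state biomasses to evaluate (kg/ha).
#' @param allow_feeding permit supplementary feeding as a decision variable.
#' @param grazing,demog,schedule model configuration.
#' @return object of class `steady_sweep`: a data frame (`z`, `income`,
#'   `objective`, `herd`, `v`, `q_f`, `q_m`, `q_c`, `feasible`) with the
#'   optimum row in `$optimum`.
#' @export
steady_state_sweep <- function(wastage_params, econ = econ_params(),
                               site = site_params(),
                               z_grid = seq(100, 6000, by = 20),
                               allow_feeding = TRUE,
                               grazing = grazing_config(),
                               demog = demography_config(),
                               schedule = season_schedule()) {
  stopifnot(all(z_grid > 0), all(z_grid <= grazing$K))
  rows <- vector("list", length(z_grid))
  for (i in seq_along(z_grid)) {
    z <- z_grid[i]
    ab <- .arboreal_daily(z, site, wastage_params, econ, grazing, demog,
                          schedule, allow_feeding)
    b <- .steady_at_z(z, site, wastage_params, econ, grazing, demog, schedule,
                      allow_feeding, ab_daily = ab)
    rows[[i]] <- if (is.null(b))
      data.frame(z = z, income = NA_real_, objective = NA_real_,
                 herd = NA_real_, v = NA_real_, q_f = NA_real_,
                 q_m = NA_real_, q_c = NA_real_, feasible = FALSE)
    else {
      nu <- max(0, b$income) / max(site$area * .site_growth(z, site, grazing),
                                   1e-12)
      data.frame(z = z, income = b$income,
                 objective = b$income - econ$interest * site$area * z * nu,
                 herd = b$N, v = b$v, q_f = b$q_f, q_m = b$q_m, q_c = b$q_c,
                 feasible = TRUE)
    }
  }
  curve <- do.call(rbind, rows)
  feas <- which(curve$feasible)
  optimum <- if (length(feas)) curve[feas[which.max(curve$objective[feas])], ]
             else NULL
  structure(list(curve = curve, optimum = optimum, econ = econ, site = site,
                 wastage = wastage_params, allow_feeding = allow_feeding),
            class = "steady_sweep")
}

# Arboreal availability per head per winter day at the steady state: the
# pool is shared by the herd, whose size itself depends on the allocation;
# a short damped fixed-point iteration resolves the circularity.
.arboreal_daily <- function(z, site, wp, econ, grazing, demog, schedule,
                            allow_feeding) {
  if (site$arboreal_pool <= 0) return(0)
  days <- schedule$days[["wi"]]
  ab <- 0
  for (it in 1:6) {
    b <- .steady_at_z(z, site, wp, econ, grazing, demog, schedule,
                      allow_feeding, ab_daily = ab,
                      v_grid = if (allow_feeding) seq(0, 450, 90) else 0,
                      qf_grid = seq(0, 0.45, 0.15), qm_grid = seq(0, 0.8, 0.4))
    if (is.null(b) || b$N <= 0) return(0)
    ab_new <- min(grazing$arboreal_cap, site$arboreal_pool / (b$N * days))
    if (abs(ab_new - ab) < 1e-9) break
    ab <- 0.5 * ab + 0.5 * ab_new
  }
  ab
}

#' @export
print.steady_sweep <- function(x, ...) {
  cat("Steady-state sweep over", nrow(x$curve), "biomass levels,",
      sum(x$curve$feasible), "feasible\n")
  if (!is.null(x$optimum))
    cat(sprintf("Optimum: z* = %g kg/ha, income = %.3g, herd = %.3g head%s\n",
                x$optimum$z, x$optimum$income, x$optimum$herd,
                if (x$optimum$v > 0)
                  sprintf(", feeding %.0f kg/head/winter", x$optimum$v)
                else ""))
  invisible(x)
}

#' @export
plot.steady_sweep <- function(x, ...) {
  ok <- x$curve$feasible
  graphics::plot(x$curve$z[ok], x$curve$income[ok], type = "l",
                 xlab = "steady-state lichen biomass (kg/ha)",
                 ylab = "yearly net income", ...)
  if (!is.null(x$optimum))
    graphics::abline(v = x$optimum$z, lty = 2)
  invisible(x)
}

# Degenerate fully-fed steady state: lichen grazed out (z ~ 0), the whole
# winter requirement supplied as feed, herd bounded by the management
# density cap instead of the lichen balance.
.fed_regime <- function(site, econ, grazing, demog, schedule) {
  pol <- .best_policy(demog$survival, demog$calving, econ, demog,
                      seq(0, 0.45, by = 0.05), seq(0, 0.8, by = 0.1))
  if (is.null(pol)) return(NULL)
  v_full <- demog$requirement_daily * schedule$days[["wi"]] / grazing$feed_sub
  N <- econ$max_density * site$area
  income <- N * (pol$meat_value_percap - econ$cost_per_head -
                   econ$feed_cost * v_full)
  list(income = income, N = N, v = v_full, policy = pol)
}

#' Supplementary-feeding frontier in (interest rate, feed cost) space
#'
#' Compares, for every grid point, the best natural-pasture steady state
#' (lichen maintained; feed at most fills winter deficits) with the
#' feeding-intensive regime (lichen grazed out, the herd wintered entirely
#' on supplementary feed). Steady states are ranked by annual net income
#' less the interest cost of the lichen capital standing in the pasture, so
#' higher interest rates disfavour keeping biomass. Reports, per interest
#' rate, the highest feed cost at which feeding is still optimal.
#'
#' @param wastage_params a [wastage_params()].
#' @param r_grid interest rates to scan.
#' @param feed_cost_grid feed costs (currency/kg) to scan.
#' @param site,econ,grazing,demog,schedule as in [steady_state_sweep()].
#' @param z_grid biomass grid for the natural-pasture optimum.
#' @return object of class `feeding_frontier`: `$classification` (logical
#'   matrix, feeding-intensive) and `$frontier` (data frame `r`,
#'   `max_feed_cost`).
#' @export
feeding_frontier <- function(wastage_params,
                             r_grid = seq(0, 0.1, by = 0.025),
                             feed_cost_grid = seq(0.01, 0.1, by = 0.01),
                             site = site_params(), econ = econ_params(),
                             grazing = grazing_config(),
                             demog = demography_config(),
                             schedule = season_schedule(),
                             z_grid = seq(200, 5600, by = 200)) {
  stopifnot(length(r_grid) > 0, length(feed_cost_grid) > 0)
  cls <- matrix(NA, length(r_grid), length(feed_cost_grid),
                dimnames = list(paste0("r=", r_grid),
                                paste0("c=", feed_cost_grid)))
  for (j in seq_along(feed_cost_grid)) {
    ec0 <- econ
    ec0$feed_cost <- feed_cost_grid[j]
    for (i in seq_along(r_grid)) {
      ec <- ec0
      ec$interest <- r_grid[i]
      sw <- steady_state_sweep(wastage_params, ec, site, z_grid,
                               allow_feeding = TRUE, grazing, demog, schedule)
      fed <- .fed_regime(site, ec, grazing, demog, schedule)
      j_nat <- if (is.null(sw$optimum)) -Inf else sw$optimum$objective
      j_fed <- if (is.null(fed)) -Inf else fed$income
      cls[i, j] <- j_fed > j_nat
    }
  }
  frontier <- data.frame(
    r = r_grid,
    max_feed_cost = vapply(seq_along(r_grid), function(i) {
      k <- which(cls[i, ])
      if (length(k)) max(feed_cost_grid[k]) else NA_real_
    }, numeric(1)))
  structure(list(classification = cls, frontier = frontier,
                 feed_cost_grid = feed_cost_grid, r_grid = r_grid),
            class = "feeding_frontier")
}

#' @export
print.feeding_frontier <- function(x, ...) {
  cat("Feeding frontier (max feed cost at which feeding is optimal):\n")
  print(x$frontier, row.names = FALSE)
  invisible(x)
}

#' Optimal steady state for one herding district
#'
#' Solves the steady-state management problem with the district's own
#' pasture parameters (area, rotation, growth rate, heavy metals,
#' infrastructure, arboreal pool) at the given interest rate, and returns
#' the optimal biomass, herd size, harvest policy and feeding intensity
#' together with the fixed-point residuals of the lichen and population
#' balances.
#'
#' @param record one district row (from a [district_set]).
#' @param wastage_params a [wastage_params()] (typically the mean
#'   cross-validated estimates).
#' @param econ an [econ_params()]; the district comparison uses
#'   `interest = 0.02`.
#' @param z_grid biomass grid.
#' @param grazing,demog,schedule model configuration.
#' @return object of class `steady_state`: the optimum row, the herd
#'   [population_state()], per-class harvest, and `residuals` (relative
#'   lichen-balance and population fixed-point errors).
#' @export
district_optimum <- function(record, wastage_params,
                             econ = econ_params(interest = 0.02),
                             z_grid = seq(50, 3000, by = 25),
                             grazing = grazing_config(),
                             demog = demography_config(),
                             schedule = season_schedule()) {
  rec <- as.list(record)
  site <- site_params(area = rec$area_lichen, rotation = isTRUE(rec$rotation),
                      g = rec$growth_rel,
                      hm = max(1e-6, 1 - rec$heavy_metal_pct / 100),
                      infra_pct = rec$infra_pct,
                      arboreal_pool = rec$arboreal_avail * rec$area_arboreal)
  sw <- steady_state_sweep(wastage_params, econ, site, z_grid,
                           allow_feeding = TRUE, grazing, demog, schedule)
  if (is.null(sw$optimum))
    return(structure(list(feasible = FALSE, sweep = sw,
                          district_id = rec$district_id),
                     class = "steady_state"))
  zo <- sw$optimum$z
  ab <- .arboreal_daily(zo, site, wastage_params, econ, grazing, demog,
                        schedule, TRUE)
  b <- .steady_at_z(zo, site, wastage_params, econ, grazing, demog, schedule,
                    TRUE, ab_daily = ab)
  B <- b$N / b$structure$heads
  pop <- population_state(B * b$structure$n_f, B * b$structure$n_m, demog)
  harvest <- list(
    females = c(b$structure$harvest_calves / 2,
                b$structure$n_f[-demog$n_female] * b$s_eff * b$q_f) * B,
    males = c(b$structure$harvest_calves / 2,
              b$structure$n_m[-demog$n_male] * b$s_eff * b$q_m) * B)
  # residuals: lichen balance and population self-replacement
  lichen_res <- abs(site$area * .site_growth(zo, site, grazing) -
                      b$N * b$cons) / max(1, site$area *
                                            .site_growth(zo, site, grazing))
  cfg2 <- demog
  nxt <- population_step(pop, b$deficit_rel, harvest, cfg2)
  # exits of the oldest classes are part of the slaughter in the stationary
  # accounting; add them back for the residual
  pop_res <- max(abs(c(nxt$females - pop$females, nxt$males - pop$males))) /
    max(1e-9, max(c(pop$females, pop$males)))
  structure(list(feasible = TRUE, district_id = rec$district_id,
                 z_opt = zo, herd = b$N, income = b$income,
                 v = b$v, q_f = b$q_f, q_m = b$q_m, q_c = b$q_c,
                 population = pop, harvest = harvest, sweep = sw,
                 residuals = c(lichen = lichen_res, population = pop_res)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  if (!x$feasible) {
    cat("District", x$district_id, ": no feasible steady state\n")
    return(invisible(x))
  }
  cat(sprintf("District %s optimum: z* = %g kg/ha, herd = %.0f, income = %.3g\n",
              x$district_id, x$z_opt, x$herd, x$income))
  invisible(x)
}

#' Compare optimal steady states with observed district data
#'
#' Counts how many districts held more reindeer in the final observed year
#' than their optimal steady-state herd, and how many had 2008 lichen
#' biomass above the optimal steady-state biomass.
#'
#' @param solutions list of [district_optimum()] results.
#' @param ds the [district_set] the solutions were computed from (needs the
#'   herd series for observed herd sizes).
#' @return a list with the comparison data frame and the counts
#'   `n_herd_above` and `n_biomass_above`.
#' @export
compare_to_data <- function(solutions, ds) {
  stopifnot(inherits(ds, "district_set"))
  d <- ds$districts
  rows <- lapply(solutions, function(s) {
    i <- match(s$district_id, d$district_id)
    hs <- corrected_herd(ds, s$district_id)
    obs_herd <- hs$total[nrow(hs)]
    data.frame(district_id = s$district_id,
               herd_observed = obs_herd,
               herd_optimal = if (s$feasible) s$herd else NA_real_,
               z_2008 = d$z_2008[i],
               z_optimal = if (s$feasible) s$z_opt else NA_real_)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       n_herd_above = sum(tab$herd_observed > tab$herd_optimal, na.rm = TRUE),
       n_biomass_above = sum(tab$z_2008 > tab$z_optimal, na.rm = TRUE))
}
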