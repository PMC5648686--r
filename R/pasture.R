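#' Seasonal wastage multipliers
#'
#' Trampling and fragmentation destroy lichen beyond what is ingested.
#' Wastage is expressed per season as a multiple of the intake rate, either
#' constant in lichen biomass or linear in it: the two parameters of the
#' linear form are the multipliers at biomass 0 and at 1,000 kg/ha, with
#' linear extrapolation above 1,000 kg/ha. Spring and autumn wastage are tied
#' to half the summer value, so only the winter and summer pairs are free.
#'
#' @param form `"constant"` or `"linear"`.
#' @param p_wi_1,p_wi_2 winter wastage-to-intake multipliers at biomass 0 and
#'   1,000 kg/ha. For the constant form give `p_wi_1` only.
#' @param p_su_1,p_su_2 summer multipliers, same convention.
#' @return an object of class `wastage_params`.
#' @examples
#' wastage_params("linear", p_wi_1 = 0, p_wi_2 = 0.7,
#'                p_su_1 = 5.7, p_su_2 = 9.6)
#' wastage_params("constant", p_wi_1 = 0.5, p_su_1 = 8.5)
#' @export
wastage_params <- function(form = c("linear", "constant"),
                           p_wi_1, p_wi_2 = p_wi_1,
                           p_su_1, p_su_2 = p_su_1) {
  form <- match.arg(form)
  if (form == "constant") {
    p_wi_2 <- p_wi_1
    p_su_2 <- p_su_1
  }
  p <- c(p_wi_1 = unname(p_wi_1), p_wi_2 = unname(p_wi_2),
         p_su_1 = unname(p_su_1), p_su_2 = unname(p_su_2))
  if (any(!is.finite(p)) || any(p < 0))
    stop("wastage multipliers must be finite and >= 0")
  structure(list(form = form, p = p), class = "wastage_params")
}

#' @export
print.wastage_params <- function(x, ...) {
  cat(sprintf("Wastage (%s form), multipliers at z = 0 / 1000 kg/ha:\n", x$form))
  cat(sprintf("  winter %.3g / %.3g   summer %.3g / %.3g   (spring = autumn = summer/2)\n",
              x$p[1], x$p[2], x$p[3], x$p[4]))
  invisible(x)
}

#' Wastage-to-intake multiplier at a given biomass
#'
#' @param params a [wastage_params] object.
#' @param z lichen biomass, kg/ha (vectorised).
#' @param season one of `"wi"`, `"sp"`, `"su"`, `"au"`.
#' @return the dimensionless multiplier `p_e1 + (p_e2 - p_e1) z / 1000`;
#'   spring and autumn return half the summer value.
#' @export
relative_wastage <- function(params, z, season = c("wi", "sp", "su", "au")) {
  season <- match.arg(season)
  if (any(z < 0)) stop("negative lichen biomass")
  p <- params$p
  w_su <- p[["p_su_1"]] + (p[["p_su_2"]] - p[["p_su_1"]]) * z / 1000
  switch(season,
         wi = p[["p_wi_1"]] + (p[["p_wi_2"]] - p[["p_wi_1"]]) * z / 1000,
         su = w_su,
         sp = 0.5 * w_su,
         au = 0.5 * w_su)
}

#' Infrastructure-induced wastage
#'
#' Roads, settlements and other disturbance concentrate reindeer movement and
#' trampling. The induced extra wastage is proportional to the disturbed
#' share of the district area, anchored so that 25% disturbance adds a
#' wastage of 1 intake-equivalent.
#'
#' @param infra_pct disturbed share of district area, percent (0-100).
#' @return the additive wastage multiplier `infra_pct / 25`.
#' @examples
#' infra_wastage(25)    # 1
#' infra_wastage(27.2)  # 1.088
#' infra_wastage(2.5)   # 0.1
#' @export
infra_wastage <- function(infra_pct) {
  if (any(!is.finite(infra_pct)) || any(infra_pct < 0) || any(infra_pct > 100))
    stop("infra_pct must be in [0, 100]")
  infra_pct / 25
}

#' Heavy-metal growth multiplier
#'
#' Airborne nickel and copper from smelters suppress lichen growth. Observed
#' moss-sample nickel concentrations are banded: no contamination leaves
#' growth unchanged, 3-6 mg/kg reduces it by 20%, 9-12 mg/kg by 40% and
#' above 15 mg/kg by 60%.
#'
#' @param nickel_band band label (`"none"`, `"3-6"`, `"9-12"`, `">15"`) or a
#'   numeric concentration in mg/kg, mapped to the nearest band.
#' @return growth multiplier 1.0, 0.8, 0.6 or 0.4.
#' @export
heavy_metal_multiplier <- function(nickel_band) {
  one <- function(b) {
    if (is.numeric(b)) {
      if (b < 3) return(1.0)
      if (b <= 7.5) return(0.8)
      if (b <= 13.5) return(0.6)
      return(0.4)
    }
    switch(as.character(b),
           "none" = 1.0, "3-6" = 0.8, "9-12" = 0.6, ">15" = 0.4,
           { warning("unknown nickel band '", b, "', assuming no reduction")
             1.0 })
  }
  vapply(nickel_band, one, numeric(1), USE.NAMES = FALSE)
}

#' Season schedule and rotation exposure
#'
#' The year is split into winter, spring, summer and autumn. Under a closed
#' pasture rotation the winter-range lichen pastures are grazed for the whole
#' winter plus four weeks of spring and are spared in summer and autumn;
#' without rotation the lichen area is exposed year-round.
#'
#' @param days named vector of season lengths in days (must sum to 365).
#' @param spring_exposure_days days of spring grazing on the winter range
#'   under rotation (default 28).
#' @return an object of class `season_schedule` with `$days` and an
#'   `$exposure(rotation)` function returning the per-season exposed fraction.
#' @export
season_schedule <- function(days = c(wi = 180, sp = 60, su = 95, au = 30),
                            spring_exposure_days = 28) {
  stopifnot(setequal(names(days), c("wi", "sp", "su", "au")),
            sum(days) == 365, all(days > 0),
            spring_exposure_days >= 0, spring_exposure_days <= days[["sp"]])
  days <- days[c("wi", "sp", "su", "au")]
  structure(list(
    days = days,
    spring_exposure_days = spring_exposure_days,
    exposure = function(rotation) {
      if (rotation) c(wi = 1, sp = spring_exposure_days / days[["sp"]],
                      su = 0, au = 0)
      else c(wi = 1, sp = 1, su = 1, au = 1)
    }), class = "season_schedule")
}

#' Grazing and lichen-growth configuration
#'
#' Houses the intake, substitution and regrowth constants of the forward
#' model. Estimated wastage multipliers scale with the intake magnitudes, so
#' these are exposed rather than hard-wired.
#'
#' @param demand per-capita daily ground-lichen intake demand (kg DM/day) per
#'   season; winter demand doubles as the winter energy requirement.
#' @param z_half half-saturation biomass of the intake functional response
#'   (kg/ha).
#' @param feed_sub kg of lichen intake spared per kg of supplementary feed.
#' @param arboreal_cap maximum arboreal lichen intake (kg/day per head).
#' @param K lichen carrying capacity (kg/ha).
#' @param r0 intrinsic lichen regrowth rate (1/yr) in mature/old pine forest.
#' @param growth `"logistic"` (`r0 z (1 - z/K)`) or `"gompertz"`
#'   (`r0 z log(K/z)`).
#' @param infra_seasons apply infrastructure wastage in `"all"` seasons or
#'   `"winter"` only.
#' @return an object of class `grazing_config`.
#' @export
grazing_config <- function(demand = c(wi = 2.0, sp = 0.4, su = 0.4, au = 0.4),
                           z_half = 300, feed_sub = 0.8, arboreal_cap = 1.5,
                           K = 6000, r0 = 0.25,
                           growth = c("logistic", "gompertz"),
                           infra_seasons = c("all", "winter")) {
  growth <- match.arg(growth)
  infra_seasons <- match.arg(infra_seasons)
  stopifnot(all(demand >= 0), z_half > 0, feed_sub >= 0, arboreal_cap >= 0,
            K > 0, r0 >= 0)
  demand <- demand[c("wi", "sp", "su", "au")]
  structure(list(demand = demand, z_half = z_half, feed_sub = feed_sub,
                 arboreal_cap = arboreal_cap, K = K, r0 = r0, growth = growth,
                 infra_seasons = infra_seasons), class = "grazing_config")
}

#' Pasture state
#'
#' @param z ground-lichen biomass on the grazed lichen area, kg/ha.
#' @param area lichen-pasture area, ha.
#' @param arboreal_pool arboreal lichen available this winter, kg
#'   (availability times arboreal area).
#' @return an object of class `pasture_state`.
#' @export
pasture_state <- function(z, area, arboreal_pool = 0) {
  stopifnot(z >= 0, area > 0, arboreal_pool >= 0)
  structure(list(z = z, area = area, arboreal_pool = arboreal_pool),
            class = "pasture_state")
}

#' Annual lichen regrowth
#'
#' Growth happens once a year, after the grazing seasons, at a rate scaled by
#' the habitat factor `g` (growth relative to mature/old pine forest) and the
#' heavy-metal multiplier.
#'
#' @param z_after_grazing biomass after the year's consumption, kg/ha.
#' @param g relative growth rate (0, 1].
#' @param hm_multiplier heavy-metal growth multiplier (see
#'   [heavy_metal_multiplier()]).
#' @param config a [grazing_config()].
#' @return kg/ha added; never negative, and never growing past `K`.
#' @export
annual_growth <- function(z_after_grazing, g, hm_multiplier,
                          config = grazing_config()) {
  z <- z_after_grazing
  stopifnot(all(z >= 0))
  G <- if (config$growth == "gompertz") {
    ifelse(z > 0, config$r0 * z * log(config$K / z), 0)
  } else {
    config$r0 * z * (1 - z / config$K)
  }
  gr <- pmax(0, g * hm_multiplier * G)
  pmin(gr, pmax(0, config$K - z))
}

#' One season of grazing removal
#'
#' Per-capita daily ground-lichen intake follows a saturating functional
#' response `demand z / (z + z_half)`, reduced (winter only) by supplementary
#' feed and by the arboreal pool. Total removal adds intake-proportional
#' wastage and infrastructure-induced wastage, is spread over the lichen
#' area, and is clamped so biomass never goes negative.
#'
#' @param state a [pasture_state()].
#' @param reindeer_days grazing pressure this season (reindeer-days).
#' @param season `"wi"`, `"sp"`, `"su"` or `"au"`.
#' @param params a [wastage_params()].
#' @param infra_pct infrastructure disturbance, percent of district area.
#' @param config a [grazing_config()].
#' @param feeding_kg supplementary feed, kg per reindeer per winter.
#' @param exposure_fraction fraction of the season the lichen area is exposed
#'   (see [season_schedule()]).
#' @param schedule a [season_schedule()].
#' @param infra_scale sensitivity multiplier on the infrastructure term.
#' @return list with `removal` (kg/ha), and a ledger: `intake_per_ha`
#'   (ingested ground lichen, kg/ha), `wastage_mult` (total multiplier W),
#'   `ground_daily`, `feed_daily`, `arboreal_daily` (per-capita kg/day),
#'   `arboreal_used` (kg), `demand_daily`, and `clamped`.
#' @export
seasonal_removal <- function(state, reindeer_days,
                             season = c("wi", "sp", "su", "au"), params,
                             infra_pct = 0, config = grazing_config(),
                             feeding_kg = 0, exposure_fraction = 1,
                             schedule = season_schedule(), infra_scale = 1) {
  season <- match.arg(season)
  stopifnot(reindeer_days >= 0, exposure_fraction >= 0, exposure_fraction <= 1)
  z <- state$z
  gi <- config$demand[[season]] * z / (z + config$z_half)
  feed_daily <- 0
  arb_daily <- 0
  arboreal_used <- 0
  if (season == "wi") {
    feed_daily <- feeding_kg * config$feed_sub / schedule$days[["wi"]]
    if (reindeer_days > 0)
      arb_daily <- min(config$arboreal_cap, state$arboreal_pool / reindeer_days)
    gi_net <- max(0, gi - feed_daily - arb_daily)
    arboreal_used <- arb_daily * reindeer_days
  } else {
    gi_net <- gi
  }
  W <- relative_wastage(params, z, season)
  if (config$infra_seasons == "all" || season == "wi")
    W <- W + infra_wastage(infra_pct) * infra_scale
  removal <- gi_net * (1 + W) * reindeer_days * exposure_fraction / state$area
  clamped <- removal > z
  if (clamped) removal <- z
  list(removal = removal,
       intake_per_ha = removal / (1 + W),
       wastage_mult = W,
       ground_daily = gi_net,
       feed_daily = feed_daily,
       arboreal_daily = arb_daily,
       arboreal_used = arboreal_used,
       demand_daily = config$demand[[season]],
       clamped = clamped)
}

#' Simulate the lichen biomass trajectory of one district
#'
#' Annual cycle: four seasonal removal steps (with rotation exposure) driven
#' by the corrected reindeer-days, then one regrowth step. The arboreal pool
#' refills each winter. Deterministic; biomass stays within `[0, K]`.
#'
#' @param record one district: a single-row data frame or list with the
#'   [district_set] columns.
#' @param herd_series a `herd_series` data frame from [corrected_herd()], or
#'   any data frame with columns `year`, `rd_wi`, `rd_sp`, `rd_su`, `rd_au`.
#' @param params a [wastage_params()].
#' @param schedule a [season_schedule()].
#' @param config a [grazing_config()].
#' @param detail if `TRUE`, attach the per-season ledger as attribute
#'   `"detail"`.
#' @param infra_scale,nickel_scale sensitivity multipliers on the
#'   infrastructure and heavy-metal terms.
#' @return data frame `year`, `z` (biomass at the start of each year,
#'   beginning with `z_1995` and ending with the prediction for 2008).
#' @export
simulate_lichen <- function(record, herd_series, params,
                            schedule = season_schedule(),
                            config = grazing_config(), detail = FALSE,
                            infra_scale = 1, nickel_scale = 1) {
  rec <- as.list(record)
  stopifnot(rec$z_1995 > 0)
  hs <- as.data.frame(herd_series)
  hs <- hs[order(hs$year), , drop = FALSE]
  seasons <- c("wi", "sp", "su", "au")
  expo <- schedule$exposure(isTRUE(rec$rotation))
  hm <- max(0, 1 - nickel_scale * rec$heavy_metal_pct / 100)
  pool0 <- rec$arboreal_avail * rec$area_arboreal
  z <- rec$z_1995
  years <- c(hs$year, max(hs$year) + 1L)
  traj <- numeric(length(years))
  traj[1] <- z
  ledger <- if (detail) vector("list", nrow(hs) * 4L)
  for (i in seq_len(nrow(hs))) {
    state <- pasture_state(z, rec$area_lichen, pool0)
    for (e in seasons) {
      out <- seasonal_removal(state, hs[[paste0("rd_", e)]][i], e, params,
                              infra_pct = rec$infra_pct, config = config,
                              feeding_kg = rec$feeding,
                              exposure_fraction = expo[[e]],
                              schedule = schedule, infra_scale = infra_scale)
      state$z <- state$z - out$removal
      if (e == "wi")
        state$arboreal_pool <- max(0, state$arboreal_pool - out$arboreal_used)
      if (detail) {
        ledger[[(i - 1L) * 4L + match(e, seasons)]] <-
          data.frame(year = hs$year[i], season = e, z = state$z,
                     removal = out$removal, intake = out$intake_per_ha,
                     wastage = out$wastage_mult)
      }
    }
    z <- state$z + annual_growth(state$z, rec$growth_rel, hm, config)
    traj[i + 1L] <- z
  }
  res <- data.frame(year = years, z = traj)
  if (detail) attr(res, "detail") <- do.call(rbind, ledger)
  res
}
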