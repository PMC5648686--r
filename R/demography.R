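#' Demographic configuration
#'
#' Rates for the age- and sex-structured herd used in optimisation mode.
#' Defaults are reconstructions exposed for sensitivity work: baseline
#' overwinter survival 0.95, calving probability 0.85 at full condition, a
#' harmonic-mean mating system in which one male can serve `sigma` females,
#' linear penalties mapping the relative winter energy deficit onto extra
#' mortality and reduced calving, and 10% calf summer mortality.
#'
#' @param survival baseline annual survival probability per class.
#' @param calving calving probability at full condition (fertile females).
#' @param sigma mating ratio: females one male can serve.
#' @param calf_mortality calf summer mortality (optimisation mode only).
#' @param penalty_mortality,penalty_calving linear coefficients: a relative
#'   winter deficit `d` multiplies survival by `1 - penalty_mortality * d`
#'   and calving by `1 - penalty_calving * d`.
#' @param n_female,n_male number of female / male age classes (ages 0 up).
#' @param fertile_min_age,mature_min_age youngest reproducing female / male
#'   age class.
#' @param requirement_daily adult wintertime energy requirement in
#'   ground-lichen equivalents (kg DM/day).
#' @param calf_requirement calf requirement as a fraction of the adult one.
#' @return a list of class `demography_config`.
#' @export
demography_config <- function(survival = 0.95, calving = 0.85, sigma = 10,
                              calf_mortality = 0.10, penalty_mortality = 1,
                              penalty_calving = 1, n_female = 17, n_male = 13,
                              fertile_min_age = 2, mature_min_age = 2,
                              requirement_daily = 2.0,
                              calf_requirement = 0.7) {
  stopifnot(survival > 0, survival <= 1, calving >= 0, calving <= 1,
            sigma > 0, calf_mortality >= 0, calf_mortality < 1,
            n_female >= 2, n_male >= 2,
            fertile_min_age >= 1, mature_min_age >= 1)
  structure(list(survival = survival, calving = calving, sigma = sigma,
                 calf_mortality = calf_mortality,
                 penalty_mortality = penalty_mortality,
                 penalty_calving = penalty_calving,
                 n_female = n_female, n_male = n_male,
                 fertile_min_age = fertile_min_age,
                 mature_min_age = mature_min_age,
                 requirement_daily = requirement_daily,
                 calf_requirement = calf_requirement),
            class = "demography_config")
}

#' Age- and sex-structured herd state
#'
#' @param females numeric vector of 17 cohort counts (ages 0-16).
#' @param males numeric vector of 13 cohort counts (ages 0-12).
#' @param config a [demography_config()] (fixes the class counts).
#' @return an object of class `population_state`.
#' @export
population_state <- function(females, males, config = demography_config()) {
  stopifnot(length(females) == config$n_female,
            length(males) == config$n_male,
            all(females >= 0), all(males >= 0))
  structure(list(females = as.numeric(females), males = as.numeric(males)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Herd: %.1f females (%d classes), %.1f males (%d classes)\n",
              sum(x$females), length(x$females),
              sum(x$males), length(x$males)))
  invisible(x)
}

#' Expected calf production under harmonic-mean mating
#'
#' `calves = calving * n_f * sigma n_m / (sigma n_m + n_f)`: male-limited
#' when males are scarce, saturating at `calving * n_f` when males are
#' abundant.
#'
#' @param n_females_fertile fertile female count.
#' @param n_males_mature mature male count.
#' @param config a [demography_config()].
#' @return expected calves (before calf summer mortality).
#' @examples
#' cfg <- demography_config(calving = 0.8, sigma = 10)
#' recruitment(100, 10, cfg)  # 40
#' @export
recruitment <- function(n_females_fertile, n_males_mature,
                        config = demography_config()) {
  stopifnot(n_females_fertile >= 0, n_males_mature >= 0)
  if (n_males_mature == 0 || n_females_fertile == 0) return(0)
  sm <- config$sigma * n_males_mature
  config$calving * n_females_fertile * sm / (sm + n_females_fertile)
}

#' Winter energy balance of a herd
#'
#' Allocates the winter energy resources to the per-class requirement in
#' optimal-foraging order: ground lichen through the saturating intake
#' response first, then the shared arboreal pool, then supplementary feed.
#' Everything is expressed in ground-lichen equivalents (kg DM per head per
#' winter).
#'
#' @param population a [population_state()].
#' @param pasture a [pasture_state()].
#' @param feed_kg_per_head supplementary feed, kg per head per winter.
#' @param config a [demography_config()].
#' @param grazing a [grazing_config()].
#' @param schedule a [season_schedule()].
#' @return list with `requirement`, `supplied`, `deficit` and `deficit_rel`
#'   per class (`$females`, `$males`), and a `ledger` of season totals
#'   (`feed`, `arboreal`, `ground`, all in kg). `supplied + deficit`
#'   reproduces `requirement` exactly.
#' @export
winter_energy_balance <- function(population, pasture, feed_kg_per_head = 0,
                                  config = demography_config(),
                                  grazing = grazing_config(),
                                  schedule = season_schedule()) {
  days <- schedule$days[["wi"]]
  ae <- list(females = c(config$calf_requirement,
                         rep(1, config$n_female - 1)),
             males = c(config$calf_requirement, rep(1, config$n_male - 1)))
  req <- lapply(ae, function(w) w * config$requirement_daily * days)
  n <- list(females = population$females, males = population$males)
  total_heads <- sum(n$females) + sum(n$males)
  total_ae <- sum(n$females * ae$females) + sum(n$males * ae$males)

  # per-adult-equivalent winter totals of each resource
  gi_ae <- grazing$demand[["wi"]] * pasture$z /
    (pasture$z + grazing$z_half) * days
  arb_ae <- if (total_ae > 0)
    min(grazing$arboreal_cap * days, pasture$arboreal_pool / total_ae) else 0
  feed_pc <- feed_kg_per_head * grazing$feed_sub   # lichen equivalents

  supplied <- deficit <- ground <- arb <- feed <- list()
  for (s in c("females", "males")) {
    gr <- pmin(req[[s]], ae[[s]] * gi_ae)
    ab <- pmin(req[[s]] - gr, ae[[s]] * arb_ae)
    fd <- pmin(req[[s]] - gr - ab, feed_pc)
    supplied[[s]] <- gr + ab + fd
    deficit[[s]] <- req[[s]] - supplied[[s]]
    ground[[s]] <- gr; arb[[s]] <- ab; feed[[s]] <- fd
  }
  tot <- function(x) sum(x$females * n$females) + sum(x$males * n$males)
  ledger <- list(ground = tot(ground), arboreal = tot(arb), feed = tot(feed),
                 heads = total_heads)
  list(requirement = req, supplied = supplied, deficit = deficit,
       deficit_rel = list(females = deficit$females / req$females,
                          males = deficit$males / req$males),
       ledger = ledger)
}

#' Advance the herd by one year
#'
#' Winter survival (reduced by the energy-deficit penalty), aging by one
#' class, autumn harvest per class, and recruitment of the calf class from
#' the harmonic-mean mating system less calf summer mortality, split evenly
#' by sex. The oldest cohorts exit after their final year (returned in the
#' `exits` attribute).
#'
#' @param state a [population_state()].
#' @param deficit relative winter energy deficit: a scalar or a list
#'   `(females, males)` of per-class fractions in \[0, 1\].
#' @param harvest list `(females, males)` of per-class removals indexed by
#'   the post-aging class (element 1 is the calf harvest).
#' @param config a [demography_config()].
#' @return the next [population_state()], with attributes `births` (calves
#'   entering after summer mortality), `deaths` (overwinter deaths),
#'   `harvest` (total removed) and `exits` (oldest-cohort exits).
#' @export
population_step <- function(state, deficit = 0,
                            harvest = list(females = NULL, males = NULL),
                            config = demography_config()) {
  defl <- if (is.list(deficit)) deficit
          else list(females = rep(deficit, config$n_female),
                    males = rep(deficit, config$n_male))
  hf <- if (is.null(harvest$females)) rep(0, config$n_female) else harvest$females
  hm <- if (is.null(harvest$males)) rep(0, config$n_male) else harvest$males
  stopifnot(length(hf) == config$n_female, length(hm) == config$n_male,
            all(hf >= 0), all(hm >= 0))

  s_f <- config$survival * pmax(0, 1 - config$penalty_mortality * defl$females)
  s_m <- config$survival * pmax(0, 1 - config$penalty_mortality * defl$males)
  fert <- (config$fertile_min_age + 1):config$n_female
  mat <- (config$mature_min_age + 1):config$n_male
  def_fert <- mean(defl$females[fert])
  c_eff_cfg <- config
  c_eff_cfg$calving <- config$calving *
    max(0, 1 - config$penalty_calving * def_fert)
  calves <- recruitment(sum(state$females[fert]), sum(state$males[mat]),
                        c_eff_cfg)
  births <- calves * (1 - config$calf_mortality)

  surv_f <- state$females * s_f
  surv_m <- state$males * s_m
  new_f <- c(births / 2, surv_f[-config$n_female]) - hf
  new_m <- c(births / 2, surv_m[-config$n_male]) - hm
  if (any(new_f < -1e-9) || any(new_m < -1e-9))
    stop("harvest exceeds available animals in some class")
  new_f <- pmax(0, new_f); new_m <- pmax(0, new_m)
  out <- population_state(new_f, new_m, config)
  attr(out, "births") <- births
  attr(out, "deaths") <- sum(state$females - surv_f) + sum(state$males - surv_m)
  attr(out, "harvest") <- sum(hf) + sum(hm)
  attr(out, "exits") <- surv_f[config$n_female] + surv_m[config$n_male]
  out
}

# Stationary herd structure per unit of annual calf production ("per-B"
# bookkeeping used by the steady-state economics). Given the effective
# survival s_eff, per-class harvest fractions q_f/q_m applied at each age
# transition and the deficit-adjusted calving rate, solves the calf-harvest
# fraction q_c that makes the population exactly self-replacing.
# Returns NULL when no q_c in [0, 1) sustains the herd.
.stationary_structure <- function(s_eff, c_eff, q_f, q_m,
                                  config = demography_config()) {
  amax_f <- config$n_female - 1L
  amax_m <- config$n_male - 1L
  r_f <- s_eff * (1 - q_f)
  r_m <- s_eff * (1 - q_m)
  ages_f <- 0:amax_f
  ages_m <- 0:amax_m
  phi_f <- sum(r_f^(config$fertile_min_age:amax_f))
  psi_m <- sum(r_m^(config$mature_min_age:amax_m))
  if (phi_f <= 0 || psi_m <= 0 || c_eff <= 0) return(NULL)
  rho <- config$sigma * psi_m / (config$sigma * psi_m + phi_f)
  keep <- 2 / ((1 - config$calf_mortality) * c_eff * phi_f * rho)
  if (!is.finite(keep) || keep > 1) return(NULL)
  q_c <- 1 - keep
  n_f <- (1 - q_c) / 2 * r_f^ages_f        # per unit B
  n_m <- (1 - q_c) / 2 * r_m^ages_m
  # harvested at each transition + terminal cull of the oldest class
  h_f <- n_f[1:amax_f] * s_eff * q_f
  h_m <- n_m[1:amax_m] * s_eff * q_m
  hf_count <- sum(h_f) + n_f[amax_f + 1] * s_eff
  hm_count <- sum(h_m) + n_m[amax_m + 1] * s_eff
  list(q_c = q_c, n_f = n_f, n_m = n_m,
       heads = sum(n_f) + sum(n_m),
       harvest_calves = q_c,                 # per unit B
       harvest_females = hf_count,
       harvest_males = hm_count)
}
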