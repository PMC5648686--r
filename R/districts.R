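#' Herding-district tables: reading, validation and herd-series correction
#'
#' A *district set* couples the per-district pasture table (one row per
#' herding district: rotation flag, supplementary feeding, ground- and
#' arboreal-lichen areas, lichen biomasses measured in 1995 and 2008, the
#' relative lichen growth rate, heavy-metal growth reduction and the share of
#' the district under infrastructure disturbance) with the annual herd series
#' (autumn census after slaughter, slaughter removals, traffic and predation
#' deaths per year and animal class).
#'
#' @name district-io
NULL

.district_cols <- c("district_id", "rotation", "feeding", "area_lichen",
                    "area_arboreal", "arboreal_avail", "z_1995", "z_2008",
                    "growth_rel", "heavy_metal_pct", "infra_pct")

.herd_cols <- c("district_id", "year", "calves_alive", "females_alive",
                "males_alive", "calves_slaughtered", "females_slaughtered",
                "males_slaughtered", "traffic_deaths", "predation_reported")

#' Construct a district set
#'
#' @param districts data frame with one row per district and the columns
#'   `district_id`, `rotation` (logical or "YES"/"NO"), `feeding`
#'   (kg supplementary feed per reindeer per winter), `area_lichen` (ha),
#'   `area_arboreal` (ha), `arboreal_avail` (kg/ha), `z_1995`, `z_2008`
#'   (kg/ha), `growth_rel` (fraction of the mature/old-pine growth rate),
#'   `heavy_metal_pct` (% growth reduction), `infra_pct` (% of district area
#'   under infrastructure disturbance).
#' @param herd optional data frame of annual herd counts with columns
#'   `district_id`, `year`, `calves_alive`, `females_alive`, `males_alive`,
#'   `calves_slaughtered`, `females_slaughtered`, `males_slaughtered`,
#'   `traffic_deaths`, `predation_reported`. Counts "alive" are autumn census
#'   counts left alive after slaughter.
#' @return an object of class `district_set`.
#' @export
district_set <- function(districts, herd = NULL) {
  districts <- as.data.frame(districts)
  missing_cols <- setdiff(.district_cols, names(districts))
  if (length(missing_cols))
    stop("district table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(districts) == 0L) stop("no districts")
  if (is.character(districts$rotation))
    districts$rotation <- toupper(trimws(districts$rotation)) %in% c("YES", "TRUE", "1")
  districts$rotation <- as.logical(districts$rotation)
  num_cols <- setdiff(.district_cols, c("district_id", "rotation"))
  for (cl in num_cols) {
    v <- districts[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !all(is.na(v) == is.na(vn)))
        stop("non-numeric value in column '", cl, "' (row ",
             which(is.na(vn) & !is.na(v))[1], ")")
      districts[[cl]] <- vn
    }
  }
  .validate_districts(districts)
  if (!is.null(herd)) {
    herd <- as.data.frame(herd)
    missing_cols <- setdiff(.herd_cols, names(herd))
    if (length(missing_cols))
      stop("herd table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    cnt <- .herd_cols[-(1:2)]
    for (cl in c("year", cnt)) herd[[cl]] <- as.numeric(herd[[cl]])
    if (any(unlist(herd[cnt]) < 0, na.rm = TRUE))
      stop("negative count in herd table")
  }
  structure(list(districts = districts, herd = herd), class = "district_set")
}

.validate_districts <- function(d) {
  chk <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad))
      stop("district table row ", bad[1], " (", d$district_id[bad[1]], "): ", msg)
  }
  chk(d$area_lichen > 0, "area_lichen must be > 0")
  chk(d$area_arboreal >= 0, "area_arboreal must be >= 0")
  chk(d$arboreal_avail >= 0, "arboreal_avail must be >= 0")
  chk(d$z_1995 > 0, "z_1995 must be > 0")
  chk(d$z_2008 > 0, "z_2008 must be > 0")
  chk(d$growth_rel > 0 & d$growth_rel <= 1, "growth_rel must be in (0, 1]")
  chk(d$heavy_metal_pct >= 0 & d$heavy_metal_pct < 100,
      "heavy_metal_pct must be in [0, 100)")
  chk(d$infra_pct >= 0 & d$infra_pct <= 100, "infra_pct must be in [0, 100]")
  chk(d$feeding >= 0, "feeding must be >= 0")
  invisible(d)
}

#' Load herding districts from delimited tables
#'
#' Reads the per-district pasture table (and optionally the annual herd
#' series) from CSV. The packaged fixture
#' `system.file("extdata", "table1_districts.csv", package = "reinpast")`
#' holds the pasture parameters of the 20 northernmost Finnish herding
#' districts (lichen biomass inventories of 1995 and 2008).
#'
#' @param table_path path to the district CSV.
#' @param herd_path optional path to the herd-series CSV.
#' @return a [district_set].
#' @examples
#' ds <- load_districts(system.file("extdata", "table1_districts.csv",
#'                                  package = "reinpast"))
#' nrow(ds$districts)  # 20
#' @export
load_districts <- function(table_path, herd_path = NULL) {
  d <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  h <- if (!is.null(herd_path)) utils::read.csv(herd_path, stringsAsFactors = FALSE)
  district_set(d, h)
}

#' Write a district set back to CSV
#'
#' Inverse of [load_districts()]; a load/write round trip reproduces the
#' table up to numeric formatting.
#'
#' @param ds a [district_set].
#' @param table_path output path for the district table.
#' @param herd_path optional output path for the herd series.
#' @export
write_districts <- function(ds, table_path, herd_path = NULL) {
  stopifnot(inherits(ds, "district_set"))
  d <- ds$districts
  d$rotation <- ifelse(d$rotation, "YES", "NO")
  utils::write.csv(d, table_path, row.names = FALSE, quote = FALSE)
  if (!is.null(herd_path) && !is.null(ds$herd))
    utils::write.csv(ds$herd, herd_path, row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' @export
print.district_set <- function(x, ...) {
  cat("District set:", nrow(x$districts), "districts",
      if (!is.null(x$herd))
        sprintf("with herd series %d-%d", min(x$herd$year), max(x$herd$year))
      else "(no herd series)", "\n")
  cat("  rotation in", sum(x$districts$rotation), "districts;",
      "lichen biomass 1995:", paste(range(x$districts$z_1995), collapse = "-"),
      "kg/ha\n")
  invisible(x)
}

#' Minimum number of uncounted reindeer
#'
#' Autumn round-ups never catch the whole herd. Comparing the number
#' reportedly left alive after slaughter in year *t* with the adults (>1 yr)
#' counted and slaughtered the next autumn, plus winter deaths, bounds the
#' number of animals that must have been missed in year *t*:
#' `max(0, adults_counted_t1 + adults_slaughtered_t1 + winter_deaths -
#' alive_after_slaughter_t)`.
#'
#' @param alive_after_slaughter_t total reindeer reported alive after
#'   slaughter in autumn of year t (all classes; that year's calves are
#'   adults by t+1).
#' @param adults_counted_t1 adults counted alive in autumn t+1.
#' @param adults_slaughtered_t1 adults slaughtered in autumn t+1.
#' @param winter_deaths deaths (traffic + predation-corrected) between the
#'   two censuses.
#' @return the minimum uncounted count (never negative). Vectorised.
#' @examples
#' min_uncounted(1000, 950, 30, 30)  # 10
#' @export
min_uncounted <- function(alive_after_slaughter_t, adults_counted_t1,
                          adults_slaughtered_t1, winter_deaths) {
  stopifnot(all(alive_after_slaughter_t >= 0), all(adults_counted_t1 >= 0),
            all(adults_slaughtered_t1 >= 0), all(winter_deaths >= 0))
  pmax(0, adults_counted_t1 + adults_slaughtered_t1 + winter_deaths -
         alive_after_slaughter_t)
}

#' Corrected herd series and seasonal grazing pressure
#'
#' Turns one district's raw annual counts into the grazing drivers of the
#' pasture simulation. Each year the census is inflated for uncounted
#' animals: the applied uncounted share is the larger of
#' `default_uncounted_share` and the share implied by [min_uncounted()]
#' bookkeeping, applied uniformly to all classes. Reported predation deaths
#' are scaled by `predation_factor` (compensation statistics assume a third
#' of carcasses are never found). Reindeer-days per season are the corrected
#' herd size times season length, with winter deaths applied as a single
#' mid-winter step.
#'
#' @param ds a [district_set] containing a herd series, or a herd data frame
#'   for a single district.
#' @param district_id district to extract when `ds` holds several.
#' @param default_uncounted_share minimum share of the herd assumed uncounted
#'   (default 0.10).
#' @param predation_factor multiplier on reported predation deaths
#'   (default 1.5).
#' @param schedule a [season_schedule()].
#' @return a data frame of class `herd_series`: per year the applied
#'   uncounted share, corrected class counts and totals, winter deaths, and
#'   reindeer-days per season (`rd_wi`, `rd_sp`, `rd_su`, `rd_au`).
#' @export
corrected_herd <- function(ds, district_id = NULL,
                           default_uncounted_share = 0.10,
                           predation_factor = 1.5,
                           schedule = season_schedule()) {
  h <- if (inherits(ds, "district_set")) ds$herd else as.data.frame(ds)
  if (is.null(h) || nrow(h) == 0L) stop("no herd series available")
  if (!is.null(district_id)) h <- h[h$district_id == district_id, , drop = FALSE]
  if (length(unique(h$district_id)) > 1L)
    stop("herd series covers several districts; give district_id")
  h <- h[order(h$year), , drop = FALSE]
  n <- nrow(h)
  alive <- h$calves_alive + h$females_alive + h$males_alive
  deaths <- h$traffic_deaths + predation_factor * h$predation_reported
  # implied share from next-autumn adult bookkeeping; last year has no
  # successor, so the default share applies there
  implied <- numeric(n)
  if (n > 1L) {
    mu <- min_uncounted(alive[-n],
                        h$females_alive[-1] + h$males_alive[-1],
                        h$females_slaughtered[-1] + h$males_slaughtered[-1],
                        deaths[-n])
    denom <- alive[-n] + mu
    bad <- denom <= 0 & mu > 0
    if (any(bad))
      stop("herd series inconsistent in year ", h$year[which(bad)[1]],
           ": implied uncounted share is 1")
    implied[-n] <- ifelse(denom > 0, mu / denom, 0)
  }
  share <- pmax(default_uncounted_share, implied)
  if (any(share >= 1)) stop("implied uncounted share reaches 1")
  corr <- 1 / (1 - share)
  total <- alive * corr
  post <- pmax(0, total - deaths)
  days <- schedule$days
  out <- data.frame(
    year = h$year,
    uncounted_share = share,
    calves = h$calves_alive * corr,
    females = h$females_alive * corr,
    males = h$males_alive * corr,
    total = total,
    winter_deaths = deaths,
    rd_wi = days[["wi"]] * (total - 0.5 * pmin(deaths, total)),
    rd_sp = days[["sp"]] * post,
    rd_su = days[["su"]] * post,
    rd_au = days[["au"]] * post)
  class(out) <- c("herd_series", "data.frame")
  out
}
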