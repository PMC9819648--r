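#' Synthetic-city scenario configuration
#'
#' Parameters for a seeded generator that emulates a mid-sized urban district:
#' ~900 residential areas and ~30 parks on a 13 x 10 km extent, partitioned
#' into 17 rectangular sub-district zones, with park area deliberately skewed
#' toward a southern band (large, well-rated parks in the south; sparse small
#' parks in the dense northern core). The skew reproduces the
#' high-accessibility-south / low-accessibility-north geography that
#' motivates equity analyses of green-space provision.
#'
#' @param seed Integer seed; every random draw flows from it.
#' @param n_demand,n_supply Site counts (defaults 902 residential areas, 31
#'   parks).
#' @param extent_km Width (east-west) and height (north-south) in km.
#' @param zone_rows Number of zone columns per row of the rectangular zone
#'   grid, south to north; must sum to the zone count (default `c(6, 6, 5)`,
#'   17 zones).
#' @param south_frac Fraction of the extent's height forming the "south"
#'   band (default 0.5).
#' @param park_area_skew Fraction of total park area (and of park count)
#'   placed in the south band; 0.5 is spatially balanced. Default 0.7.
#' @param pop_meanlog,pop_sdlog Log-normal parameters for residential
#'   populations (default median 1000 persons).
#' @param area_meanlog,area_sdlog Log-normal parameters for park areas in
#'   square meters (default median 3 ha).
#' @param score_bounds Uniform bounds for park quality scores (default 3.5-5,
#'   a 0-5 rating scale).
#' @param threshold_minutes Catchment travel-time threshold (default 39).
#' @param modes,mode_shares Travel modes and daily-trip shares (default
#'   [default_mode_mix()]).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 42L,
                            n_demand = 902L,
                            n_supply = 31L,
                            extent_km = c(13, 10),
                            zone_rows = c(6L, 6L, 5L),
                            south_frac = 0.5,
                            park_area_skew = 0.7,
                            pop_meanlog = log(1000), pop_sdlog = 0.6,
                            area_meanlog = log(30000), area_sdlog = 1.0,
                            score_bounds = c(3.5, 5),
                            threshold_minutes = 39,
                            modes = c("driving", "transit", "riding", "walking"),
                            mode_shares = c(0.257, 0.432, 0.086, 0.225)) {
  stopifnot(n_demand > 0, n_supply > 0, length(extent_km) == 2,
            all(extent_km > 0), all(zone_rows > 0),
            south_frac > 0, south_frac < 1,
            park_area_skew >= 0, park_area_skew <= 1,
            score_bounds[1] > 0, score_bounds[2] >= score_bounds[1],
            threshold_minutes > 0, length(modes) == length(mode_shares))
  structure(list(seed = as.integer(seed), n_demand = as.integer(n_demand),
                 n_supply = as.integer(n_supply), extent_km = extent_km,
                 zone_rows = as.integer(zone_rows), south_frac = south_frac,
                 park_area_skew = park_area_skew,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 score_bounds = score_bounds,
                 threshold_minutes = threshold_minutes,
                 mix = mode_mix(modes, mode_shares)),
            class = "scenario_config")
}

#' Generate a synthetic city
#'
#' Draws residential areas (uniform locations, log-normal populations) and
#' parks (log-normal areas, uniform quality scores) on the configured extent.
#' Park placement and area are skewed to the south band: a `park_area_skew`
#' fraction of the parks is located there and the drawn areas are rescaled so
#' that the south band holds exactly that fraction of the total park area.
#' Zones are a rectangular partition of the extent. Fully deterministic under
#' the config seed.
#'
#' @param config A [scenario_config()].
#' @return List with `demand` ([demand_sites()]), `supply` ([supply_sites()]),
#'   `zones` (data frame of zone rectangles: `zone_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax`) and the `config`.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  W <- config$extent_km[1] * 1000
  H <- config$extent_km[2] * 1000
  ysplit <- config$south_frac * H
  zones <- zone_grid(W, H, config$zone_rows)

  nd <- config$n_demand
  dem <- data.frame(
    site_id = sprintf("r%04d", seq_len(nd)),
    x = stats::runif(nd, 0, W),
    y = stats::runif(nd, 0, H),
    population = stats::rlnorm(nd, config$pop_meanlog, config$pop_sdlog)
  )
  dem$zone_id <- assign_zone(dem$x, dem$y, zones)

  ns <- config$n_supply
  skew <- config$park_area_skew
  n_south <- if (skew <= 0) 0L else if (skew >= 1) ns else
    max(1L, min(ns - 1L, as.integer(round(skew * ns))))
  south <- c(rep(TRUE, n_south), rep(FALSE, ns - n_south))
  sx <- stats::runif(ns, 0, W)
  sy <- ifelse(south, stats::runif(ns, 0, ysplit), stats::runif(ns, ysplit, H))
  area <- stats::rlnorm(ns, config$area_meanlog, config$area_sdlog)
  if (n_south > 0L && n_south < ns) {
    # rescale so the south band holds exactly the configured area share
    tot <- sum(area)
    s_south <- sum(area[south])
    area[south] <- area[south] * skew * tot / s_south
    area[!south] <- area[!south] * (1 - skew) * tot / (tot - s_south)
  }
  score <- stats::runif(ns, config$score_bounds[1], config$score_bounds[2])
  sup <- data.frame(site_id = sprintf("p%03d", seq_len(ns)),
                    x = sx, y = sy, supply_scale = area, weight = score)

  list(demand = demand_sites(dem), supply = supply_sites(sup),
       zones = zones, config = config)
}

zone_grid <- function(W, H, zone_rows) {
  nrows <- length(zone_rows)
  ybreaks <- seq(0, H, length.out = nrows + 1)
  out <- list()
  z <- 0L
  for (r in seq_len(nrows)) {
    xbreaks <- seq(0, W, length.out = zone_rows[r] + 1)
    for (cc in seq_len(zone_rows[r])) {
      z <- z + 1L
      out[[z]] <- data.frame(zone_id = sprintf("Z%02d", z),
                             xmin = xbreaks[cc], xmax = xbreaks[cc + 1],
                             ymin = ybreaks[r], ymax = ybreaks[r + 1])
    }
  }
  do.call(rbind, out)
}

assign_zone <- function(x, y, zones) {
  zid <- rep(NA_character_, length(x))
  for (r in seq_len(nrow(zones))) {
    inside <- x >= zones$xmin[r] & x <= zones$xmax[r] &
      y >= zones$ymin[r] & y <= zones$ymax[r] & is.na(zid)
    zid[inside] <- zones$zone_id[r]
  }
  zid
}

#' Default mode speed models for the synthetic city
#'
#' Kinematic travel-time models calibrated to typical 39-minute reach
#' envelopes: walking covers about 2.7 km and riding about 7 km in 39
#' minutes, while driving (40 km/h) covers the whole 13 x 10 km extent.
#' Transit rides three corridors crossing the extent (35 km/h, 3-minute
#' boarding overhead) with walking access, so its reach follows the corridor
#' geometry.
#'
#' @param config A [scenario_config()].
#' @return Named list of [mode_speed_model()]s for the config's modes.
#' @export
default_speed_models <- function(config) {
  W <- config$extent_km[1] * 1000
  H <- config$extent_km[2] * 1000
  walk_kmh <- 60 * 2.7 / 39  # 2.7 km in 39 min
  ride_kmh <- 60 * 7 / 39    # 7 km in 39 min
  corridors <- list(
    cbind(c(W / 2, W / 2), c(0, H)),          # north-south trunk
    cbind(c(0, W), c(H / 2, H / 2)),          # east-west trunk
    cbind(c(0, W), c(0, H))                   # diagonal line
  )
  models <- list(
    driving = mode_speed_model("driving", cruise_speed_kmh = 40),
    transit = mode_speed_model("transit", cruise_speed_kmh = 35,
                               fixed_overhead_min = 3,
                               corridors = corridors,
                               corridor_access_kmh = walk_kmh),
    riding  = mode_speed_model("riding", cruise_speed_kmh = ride_kmh),
    walking = mode_speed_model("walking", cruise_speed_kmh = walk_kmh)
  )
  models[config$mix$modes]
}

#' Per-mode travel-time matrices for a synthetic city
#'
#' Applies the default (or supplied) speed models to the city's demand and
#' supply sites.
#'
#' @param city Output of [generate_city()].
#' @param models Optional named list of [mode_speed_model()]s; defaults to
#'   [default_speed_models()].
#' @return Named list of [cost_matrix()] objects, one per mode.
#' @export
generate_mode_costs <- function(city, models = NULL) {
  if (is.null(models)) models <- default_speed_models(city$config)
  lapply(models, function(m) speed_time_matrix(city$demand, city$supply, m))
}

#' Run the full model on a synthetic scenario
#'
#' Convenience wrapper: generate the city, build per-mode travel times, run
#' the supply-competition multimodal pipeline at the configured threshold.
#'
#' @param config A [scenario_config()].
#' @param decay_kind `"gaussian"` (default) or `"indicator"`.
#' @param use_weights Use park quality weights? Default TRUE.
#' @return List: `city`, `costs`, and the [run_scm_g2sfca()] `result`.
#' @export
run_synthetic_scenario <- function(config = scenario_config(),
                                   decay_kind = "gaussian",
                                   use_weights = TRUE) {
  city <- generate_city(config)
  costs <- generate_mode_costs(city)
  dec <- decay_spec(decay_kind, config$threshold_minutes)
  res <- run_scm_g2sfca(city$demand, city$supply, costs, dec,
                        city$config$mix, use_weights)
  list(city = city, costs = costs, result = res)
}

#' South/north band population-weighted mean accessibility
#'
#' Diagnostic for the synthetic scenario's intended geography: the
#' population-weighted mean of an accessibility field over demand sites in
#' the south band versus the rest.
#'
#' @param field `accessibility_field` or named vector.
#' @param city Output of [generate_city()].
#' @return Named numeric: `south`, `north`.
#' @export
band_means <- function(field, city) {
  vals <- field_values(field)
  dem <- city$demand
  a <- vals[dem$site_id]
  ysplit <- city$config$south_frac * city$config$extent_km[2] * 1000
  south <- dem$y < ysplit
  c(south = sum((dem$population * a)[south]) / sum(dem$population[south]),
    north = sum((dem$population * a)[!south]) / sum(dem$population[!south]))
}
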