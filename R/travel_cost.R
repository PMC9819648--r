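#' Euclidean distance matrix (baseline cost)
#'
#' Straight-line demand-by-supply distances in the planar coordinate unit.
#' Used for the distance-threshold G2SFCA baseline that ignores the transport
#' network.
#'
#' @param demand,supply Site tables.
#' @return A [cost_matrix()] with `metric = "euclidean"`.
#' @export
euclidean_matrix <- function(demand, supply) {
  stopifnot(inherits(demand, "demand_sites"), inherits(supply, "supply_sites"))
  dx <- outer(demand$x, supply$x, "-")
  dy <- outer(demand$y, supply$y, "-")
  cost_matrix(sqrt(dx^2 + dy^2), mode = "euclidean", metric = "euclidean",
              demand_ids = demand$site_id, supply_ids = supply$site_id)
}

#' Mode speed model
#'
#' A simple kinematic stand-in for navigation-derived travel times: a cruise
#' speed over the straight-line distance plus a fixed access/egress overhead.
#' Transit modes additionally carry corridor polylines (subway/bus lines): a
#' trip may walk straight to a corridor, ride along it, and walk off, and the
#' cheapest of that and the pure walk is used. Coordinates are meters; speeds
#' km/h; overheads and resulting costs minutes.
#'
#' @param mode Mode label.
#' @param cruise_speed_kmh Cruise speed, must be positive.
#' @param fixed_overhead_min Fixed access/egress minutes added to every
#'   corridor/drive trip (e.g. parking, stop wait). Default 0.
#' @param corridors Optional list of corridor polylines, each a two-column
#'   matrix of vertex coordinates (meters). Presence makes the mode a transit
#'   mode.
#' @param corridor_access_kmh Walking speed for corridor access/egress legs
#'   and for the pure-walk fallback. Required when `corridors` is given.
#' @return A `mode_speed_model`.
#' @export
mode_speed_model <- function(mode, cruise_speed_kmh, fixed_overhead_min = 0,
                             corridors = NULL, corridor_access_kmh = NULL) {
  if (!is.numeric(cruise_speed_kmh) || cruise_speed_kmh <= 0) {
    stop("cruise_speed_kmh must be > 0", call. = FALSE)
  }
  if (fixed_overhead_min < 0) stop("fixed_overhead_min must be >= 0", call. = FALSE)
  if (!is.null(corridors)) {
    if (is.null(corridor_access_kmh) || corridor_access_kmh <= 0) {
      stop("corridor_access_kmh must be > 0 for transit modes", call. = FALSE)
    }
    corridors <- lapply(corridors, function(p) {
      p <- as.matrix(p)
      stopifnot(ncol(p) == 2, nrow(p) >= 2)
      p
    })
  }
  structure(list(mode = mode, cruise_speed_kmh = cruise_speed_kmh,
                 fixed_overhead_min = fixed_overhead_min,
                 corridors = corridors,
                 corridor_access_kmh = corridor_access_kmh),
            class = "mode_speed_model")
}

#' Travel-time matrix from a speed model
#'
#' Non-transit modes: `minutes = overhead + 60 * distance_km / cruise_speed`.
#' Transit modes: for each origin-destination pair, the minimum over the pure
#' walk and, per corridor, walk to the nearest corridor point, ride along the
#' corridor between the two projection points at cruise speed (plus overhead),
#' and walk off. Transfers between corridors are not modeled.
#'
#' @param demand,supply Site tables.
#' @param model A [mode_speed_model()].
#' @return A [cost_matrix()] in minutes.
#' @export
speed_time_matrix <- function(demand, supply, model) {
  stopifnot(inherits(model, "mode_speed_model"))
  dist_m <- sqrt(outer(demand$x, supply$x, "-")^2 +
                 outer(demand$y, supply$y, "-")^2)
  if (is.null(model$corridors)) {
    minutes <- model$fixed_overhead_min +
      60 * (dist_m / 1000) / model$cruise_speed_kmh
  } else {
    walk <- 60 * (dist_m / 1000) / model$corridor_access_kmh
    minutes <- walk
    for (line in model$corridors) {
      pd <- project_to_polyline(demand$x, demand$y, line)
      ps <- project_to_polyline(supply$x, supply$y, line)
      ride_m <- abs(outer(pd$chainage, ps$chainage, "-"))
      opt <- model$fixed_overhead_min +
        60 * (outer(pd$offset, rep(1, nrow(supply))) / 1000) / model$corridor_access_kmh +
        60 * (ride_m / 1000) / model$cruise_speed_kmh +
        60 * (outer(rep(1, nrow(demand)), ps$offset) / 1000) / model$corridor_access_kmh
      minutes <- pmin(minutes, opt)
    }
  }
  cost_matrix(minutes, mode = model$mode, metric = "time",
              demand_ids = demand$site_id, supply_ids = supply$site_id)
}

# Project points onto a polyline: returns the perpendicular offset (meters)
# and the arc-length position (chainage) of the nearest point on the line.
project_to_polyline <- function(x, y, line) {
  nseg <- nrow(line) - 1L
  seglen <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  cum0 <- c(0, cumsum(seglen))[seq_len(nseg)]
  best_off <- rep(Inf, length(x))
  best_chain <- numeric(length(x))
  for (s in seq_len(nseg)) {
    ax <- line[s, 1]; ay <- line[s, 2]
    vx <- line[s + 1, 1] - ax; vy <- line[s + 1, 2] - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    px <- ax + t * vx; py <- ay + t * vy
    off <- sqrt((x - px)^2 + (y - py)^2)
    better <- off < best_off
    best_off[better] <- off[better]
    best_chain[better] <- cum0[s] + t[better] * sqrt(L2)
  }
  list(offset = best_off, chainage = best_chain)
}

#' Destinations reachable within a threshold
#'
#' The catchment of one origin: all destination ids whose cost from the origin
#' is within the threshold (inclusive).
#'
#' @param costs A [cost_matrix()].
#' @param origin_site A demand site id (row of the matrix).
#' @param threshold Catchment threshold in the matrix's cost unit.
#' @return Character vector of destination site ids.
#' @export
reachable_set <- function(costs, origin_site, threshold) {
  stopifnot(inherits(costs, "cost_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a single nonnegative number", call. = FALSE)
  }
  origin_site <- as.character(origin_site)
  if (!origin_site %in% rownames(costs)) {
    stop(sprintf("unknown origin site: %s", origin_site), call. = FALSE)
  }
  row <- unclass(costs)[origin_site, ]
  names(row)[row <= threshold]
}
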