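#' Demand sites (residential areas)
#'
#' Validates and normalizes a table of demand locations. Each row is a
#' residential area with planar coordinates, a population (the demand scale
#' \eqn{D_i}), and an optional zone (sub-district) membership used for
#' aggregation. Rows are sorted by `site_id` so every downstream accumulation
#' runs in a fixed, reproducible order.
#'
#' @param df Data frame with columns `site_id`, `x`, `y`, `population` and
#'   optionally `zone_id`. Coordinates must be planar projected units (meters
#'   recommended); no lat/lon math happens anywhere in the engine.
#' @return A `demand_sites` data frame sorted by `site_id`.
#' @export
demand_sites <- function(df) {
  df <- as.data.frame(df)
  need <- c("site_id", "x", "y", "population")
  check_columns(df, need, "demand")
  df$site_id <- as.character(df$site_id)
  check_ids(df$site_id, "demand")
  check_coords(df, "demand")
  bad <- which(!is.finite(df$population) | df$population < 0)
  if (length(bad)) {
    stop(sprintf("demand row %d (site_id=%s): population must be finite and >= 0",
                 bad[1], df$site_id[bad[1]]), call. = FALSE)
  }
  if (!"zone_id" %in% names(df)) df$zone_id <- NA_character_
  df$zone_id <- as.character(df$zone_id)
  df <- df[order(df$site_id), c("site_id", "x", "y", "population", "zone_id")]
  rownames(df) <- NULL
  class(df) <- c("demand_sites", "data.frame")
  df
}

#' Supply sites (parks)
#'
#' Validates and normalizes a table of supply locations. Each row is a park
#' with a supply scale \eqn{S_j} (the park area) and a competition weight
#' \eqn{W_j} (a quality score such as a crowd-sourced rating) that multiplies
#' capacity in the supply-competition model. Weights are used raw, not
#' normalized; see [rescale_scores()] for an optional min-max rescaling.
#'
#' @param df Data frame with columns `site_id`, `x`, `y`, `supply_scale`,
#'   `weight` (the aliases `area` and `score` are accepted and renamed).
#' @return A `supply_sites` data frame sorted by `site_id`.
#' @export
supply_sites <- function(df) {
  df <- as.data.frame(df)
  if ("area" %in% names(df) && !"supply_scale" %in% names(df)) {
    names(df)[names(df) == "area"] <- "supply_scale"
  }
  if ("score" %in% names(df) && !"weight" %in% names(df)) {
    names(df)[names(df) == "score"] <- "weight"
  }
  need <- c("site_id", "x", "y", "supply_scale", "weight")
  check_columns(df, need, "supply")
  df$site_id <- as.character(df$site_id)
  check_ids(df$site_id, "supply")
  check_coords(df, "supply")
  bad <- which(!is.finite(df$supply_scale) | df$supply_scale <= 0)
  if (length(bad)) {
    stop(sprintf("supply row %d (site_id=%s): supply_scale must be > 0",
                 bad[1], df$site_id[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad)) {
    stop(sprintf("supply row %d (site_id=%s): weight must be > 0",
                 bad[1], df$site_id[bad[1]]), call. = FALSE)
  }
  df <- df[order(df$site_id), need]
  rownames(df) <- NULL
  class(df) <- c("supply_sites", "data.frame")
  df
}

#' Min-max rescale supply quality scores to [0, 1]
#'
#' Optional preprocessing for the competition weights. Off by default in the
#' pipeline: the model is homogeneous in the weights, so raw scores only set
#' the overall scale of the accessibility field.
#'
#' @param supply A `supply_sites` table.
#' @param lower,upper Target range (weights of 0 are disallowed, so `lower`
#'   must be positive).
#' @return The table with `weight` rescaled.
#' @export
rescale_scores <- function(supply, lower = 0.01, upper = 1) {
  stopifnot(inherits(supply, "supply_sites"), lower > 0, upper > lower)
  w <- supply$weight
  rng <- range(w)
  if (rng[1] == rng[2]) {
    supply$weight <- rep(upper, length(w))
  } else {
    supply$weight <- lower + (w - rng[1]) / (rng[2] - rng[1]) * (upper - lower)
  }
  supply
}

#' Travel-cost matrix
#'
#' A dense demand-by-supply matrix of nonnegative travel costs for one mode,
#' with `Inf` as the unreachable sentinel (always outside every catchment).
#' Rows are demand sites, columns supply sites, both identified by dimnames.
#'
#' @param cost Numeric matrix; entries nonnegative, `Inf` allowed, `NA` not.
#' @param mode Mode label (e.g. `"walking"`), or `"euclidean"` for a
#'   distance baseline.
#' @param metric `"time"` (minutes) or `"euclidean"` (planar distance units).
#' @param demand_ids,supply_ids Row/column ids; taken from `dimnames(cost)`
#'   when omitted.
#' @return A `cost_matrix` object.
#' @export
cost_matrix <- function(cost, mode, metric = c("time", "euclidean"),
                        demand_ids = NULL, supply_ids = NULL) {
  metric <- match.arg(metric)
  cost <- as.matrix(cost)
  if (!is.null(demand_ids)) rownames(cost) <- as.character(demand_ids)
  if (!is.null(supply_ids)) colnames(cost) <- as.character(supply_ids)
  if (is.null(rownames(cost)) || is.null(colnames(cost))) {
    stop("cost matrix needs demand/supply site ids as dimnames", call. = FALSE)
  }
  if (anyNA(cost)) stop("cost matrix contains NA/NaN", call. = FALSE)
  if (any(cost < 0)) stop("cost matrix has negative entries", call. = FALSE)
  structure(cost, mode = mode, metric = metric,
            class = c("cost_matrix", "matrix", "array"))
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix> mode=%s metric=%s %d demand x %d supply\n",
              attr(x, "mode"), attr(x, "metric"), nrow(x), ncol(x)))
  invisible(x)
}

#' Travel-mode mix
#'
#' Ordered travel modes and their daily-trip shares, used as convex weights
#' when compositing per-mode accessibility fields. Shares are renormalized to
#' sum to 1 at construction; a deviation beyond `1e-6` triggers a warning
#' (a mode-split table quoted in percent should sum to 100 exactly, but user
#' configurations may not).
#'
#' @param modes Character vector of mode labels.
#' @param shares Nonnegative shares, one per mode.
#' @return A `mode_mix` object with normalized shares.
#' @export
mode_mix <- function(modes, shares) {
  modes <- as.character(modes)
  if (length(modes) != length(shares)) {
    stop("`modes` and `shares` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(modes)) stop("duplicate mode labels", call. = FALSE)
  if (!is.numeric(shares) || anyNA(shares) || any(shares < 0)) {
    stop("shares must be nonnegative numbers", call. = FALSE)
  }
  s <- sum(shares)
  if (s <= 0) stop("shares sum to zero", call. = FALSE)
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("mode shares sum to %.6g; renormalizing to 1", s),
            call. = FALSE)
  }
  structure(list(modes = modes, shares = as.numeric(shares) / s),
            class = "mode_mix")
}

#' Default mode split: driving, public transportation, riding, walking
#'
#' Daily-trip shares for a large inland Chinese city: driving 25.7%, public
#' transportation 43.2%, riding 8.6%, walking 22.5%.
#'
#' @return A `mode_mix` with four modes.
#' @export
default_mode_mix <- function() {
  mode_mix(c("driving", "transit", "riding", "walking"),
           c(0.257, 0.432, 0.086, 0.225))
}

#' @export
print.mode_mix <- function(x, ...) {
  cat("<mode_mix>\n")
  for (i in seq_along(x$modes)) {
    cat(sprintf("  %-10s %6.3f\n", x$modes[i], x$shares[i]))
  }
  invisible(x)
}

# ---- shared validators ----

check_columns <- function(df, need, role) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s",
                 role, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

check_ids <- function(ids, role) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("%s table has empty site_id", role), call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("%s table has duplicate site_id: %s", role, dup[1]),
         call. = FALSE)
  }
}

check_coords <- function(df, role) {
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) {
    stop(sprintf("%s row %d (site_id=%s): non-finite coordinates",
                 role, bad[1], df$site_id[bad[1]]), call. = FALSE)
  }
}
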