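#' Population-weighted zone aggregation
#'
#' Aggregates a per-site accessibility field to zones (sub-districts) by the
#' population-weighted mean: zone value = sum(D_i A_i) / sum(D_i) over the
#' zone's demand sites. A zone whose total population is zero has no defined
#' weighted mean and is reported as `NA` with a warning.
#'
#' @param field An `accessibility_field` (or a named numeric vector keyed by
#'   site id).
#' @param demand A [demand_sites()] table carrying `zone_id` for every site.
#' @return Data frame with `zone_id`, `value`, `total_population`.
#' @export
aggregate_by_zone <- function(field, demand) {
  vals <- field_values(field)
  stopifnot(inherits(demand, "demand_sites"))
  if (anyNA(demand$zone_id)) {
    stop("every demand site must carry a zone_id for aggregation", call. = FALSE)
  }
  if (!setequal(names(vals), demand$site_id)) {
    stop("field sites do not match demand sites", call. = FALSE)
  }
  a <- vals[demand$site_id]
  pop <- demand$population
  zones <- sort(unique(demand$zone_id))
  num <- vapply(zones, function(z) sum((pop * a)[demand$zone_id == z]), 0)
  den <- vapply(zones, function(z) sum(pop[demand$zone_id == z]), 0)
  if (any(den == 0)) {
    warning(sprintf("zone(s) with zero total population reported as NA: %s",
                    paste(zones[den == 0], collapse = ", ")), call. = FALSE)
  }
  data.frame(zone_id = zones,
             value = ifelse(den == 0, NA_real_, num / den),
             total_population = den,
             row.names = NULL, stringsAsFactors = FALSE)
}

field_values <- function(field) {
  if (inherits(field, "accessibility_field")) return(field$values)
  if (is.numeric(field) && !is.null(names(field))) return(field)
  stop("expected an accessibility_field or a named numeric vector",
       call. = FALSE)
}

#' Spatial weights from site coordinates
#'
#' Builds a neighbor structure for Moran statistics: k-nearest-neighbor
#' (Euclidean, distance ties broken by site id) or a fixed distance band.
#' Weights are binary and, by default, row-standardized so each site's
#' neighbor weights sum to 1. Sites never neighbor themselves.
#'
#' @param sites Data frame with `site_id`, `x`, `y` (a [demand_sites()] table
#'   works).
#' @param scheme `"knn"` or `"distance_band"`.
#' @param k Number of neighbors for knn (default 8, common LISA practice).
#' @param band Radius for `distance_band`, in coordinate units.
#' @param row_standardize Divide each row by its neighbor count? Default TRUE.
#' @return A `spatial_weights` object: site ids plus per-site integer neighbor
#'   indices and weights.
#' @export
build_weights <- function(sites, scheme = c("knn", "distance_band"), k = 8,
                          band = NULL, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  sites <- as.data.frame(sites)
  check_columns(sites, c("site_id", "x", "y"), "weights")
  ids <- as.character(sites$site_id)
  check_ids(ids, "weights")
  o <- order(ids)
  ids <- ids[o]
  x <- sites$x[o]; y <- sites$y[o]
  n <- length(ids)
  if (scheme == "knn") {
    if (k < 1 || k >= n) stop("need 1 <= k < number of sites", call. = FALSE)
  } else {
    if (is.null(band) || band <= 0) stop("distance_band needs band > 0", call. = FALSE)
  }
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    if (scheme == "knn") {
      # order by distance, ties by sorted-id position: deterministic
      nb <- order(d, seq_len(n))[seq_len(k)]
    } else {
      nb <- which(d <= band)
    }
    neighbors[[i]] <- sort(nb)
  }
  weights <- lapply(neighbors, function(nb) {
    if (!length(nb)) return(numeric(0))
    if (row_standardize) rep(1 / length(nb), length(nb)) else rep(1, length(nb))
  })
  structure(list(ids = ids, neighbors = neighbors, weights = weights,
                 scheme = scheme, row_standardized = row_standardize),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %s, %d sites, row_standardized=%s\n",
              x$scheme, length(x$ids), x$row_standardized))
  invisible(x)
}

# Spatial lag of a value vector already aligned to w$ids.
spatial_lag <- function(w, z) {
  vapply(seq_along(z),
         function(i) sum(w$weights[[i]] * z[w$neighbors[[i]]]), 0)
}

align_field_to_weights <- function(values, w) {
  if (is.null(names(values))) {
    if (length(values) != length(w$ids)) {
      stop("unnamed values must match the number of weight sites", call. = FALSE)
    }
    names(values) <- w$ids
  }
  if (!setequal(names(values), w$ids)) {
    stop("value names do not match weights' site ids", call. = FALSE)
  }
  values[w$ids]
}

#' Global Moran's I
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with mean-centered values \eqn{z} and \eqn{S_0} the sum of all weights.
#'
#' @param values Named numeric vector keyed by site id (or an
#'   `accessibility_field`).
#' @param weights A [build_weights()] object.
#' @return The Moran statistic (scalar).
#' @export
global_moran <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  v <- align_field_to_weights(field_values(values), weights)
  n <- length(v)
  if (n < 3) stop("need at least 3 sites", call. = FALSE)
  z <- v - mean(v)
  if (sum(z^2) == 0) stop("constant field: Moran's I undefined", call. = FALSE)
  s0 <- sum(unlist(weights$weights))
  lag <- spatial_lag(weights, z)
  (n / s0) * sum(z * lag) / sum(z^2)
}

#' Local Moran's I with LISA cluster classification
#'
#' Per-site local Moran statistic
#' \eqn{I_i = (z_i / m_2) \sum_j w_{ij} z_j} with \eqn{m_2 = \sum_i z_i^2/n},
#' tested by conditional permutation: the value at site i stays fixed while
#' the remaining values are drawn without replacement into its neighbor slots.
#' The two-tailed pseudo p-value is `(#{|I_perm| >= |I_obs|} + 1)/(n_perm + 1)`.
#' Significant sites are classified by the signs of their own deviation and
#' their spatial lag: high surrounded by high (HH), low-low (LL), and the
#' high-low / low-high outliers; all others are "not significant".
#'
#' Permutations are drawn in sorted-site-id order from one seeded generator,
#' so results are reproducible and invariant to the input row order. A
#' constant field yields all "not significant" with a warning instead of a
#' division by zero.
#'
#' @inheritParams global_moran
#' @param n_perm Number of conditional permutations (>= 99; default 999).
#' @param seed Integer seed, required (permutation inference must be
#'   reproducible).
#' @param alpha Significance level for cluster labeling (default 0.05).
#' @return A `lisa_result` data frame: `site_id`, `I_local`, `p_pseudo`,
#'   `cluster` in `HH`, `LL`, `HL`, `LH`, `not significant`.
#' @export
local_moran <- function(values, weights, n_perm = 999, seed, alpha = 0.05) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is required for permutation inference", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  v <- align_field_to_weights(field_values(values), weights)
  n <- length(v)
  if (n < 3) stop("need at least 3 sites", call. = FALSE)
  z <- v - mean(v)
  out <- data.frame(site_id = weights$ids, I_local = NA_real_,
                    p_pseudo = NA_real_, cluster = "not significant",
                    row.names = NULL, stringsAsFactors = FALSE)
  if (sum(z^2) == 0) {
    warning("constant field: all sites labeled not significant", call. = FALSE)
    out$I_local <- 0
    out$p_pseudo <- 1
    class(out) <- c("lisa_result", "data.frame")
    return(out)
  }
  m2 <- sum(z^2) / n
  lag <- spatial_lag(weights, z)
  I_obs <- (z / m2) * lag

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  p <- numeric(n)
  for (i in seq_len(n)) {
    nb_w <- weights$weights[[i]]
    kni <- length(nb_w)
    if (kni == 0) { p[i] <- 1; next }
    pool <- z[-i]
    # n_perm draws of kni values without replacement from the other n-1 sites
    draws <- matrix(0, n_perm, kni)
    for (r in seq_len(n_perm)) {
      draws[r, ] <- pool[sample.int(n - 1L, kni)]
    }
    lag_perm <- as.vector(draws %*% nb_w)
    I_perm <- (z[i] / m2) * lag_perm
    p[i] <- (sum(abs(I_perm) >= abs(I_obs[i])) + 1) / (n_perm + 1)
  }

  cluster <- rep("not significant", n)
  sig <- p < alpha
  cluster[sig & z > 0 & lag > 0] <- "HH"
  cluster[sig & z < 0 & lag < 0] <- "LL"
  cluster[sig & z > 0 & lag < 0] <- "HL"
  cluster[sig & z < 0 & lag > 0] <- "LH"
  out$I_local <- I_obs
  out$p_pseudo <- p
  out$cluster <- cluster
  class(out) <- c("lisa_result", "data.frame")
  out
}
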