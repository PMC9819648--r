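# Shared builders and independent oracles for the test suite.

toy_demand <- function() {
  demand_sites(data.frame(
    site_id = c("r1", "r2", "r3"),
    x = c(0, 1000, 2000), y = c(0, 0, 0),
    population = c(100, 200, 300),
    zone_id = c("north", "north", "south")))
}

toy_supply <- function() {
  supply_sites(data.frame(
    site_id = c("p1", "p2"),
    x = c(200, 1800), y = c(0, 0),
    supply_scale = c(10, 20), weight = c(1, 1)))
}

# Travel minutes matching the 3x2 worked example checked by hand:
# catchments at t0 = 39 are p1 <- {r1, r2}, p2 <- {r2, r3}.
toy_costs <- function(mode = "walking") {
  cost_matrix(matrix(c(10, 20, 45,
                       50, 30, 15), nrow = 3),
              mode = mode, metric = "time",
              demand_ids = c("r1", "r2", "r3"),
              supply_ids = c("p1", "p2"))
}

# Random small instance; all costs bounded so catchments can be forced
# nonempty via max_cost < threshold.
random_instance <- function(n_demand, n_supply, max_cost = 35) {
  dem <- demand_sites(data.frame(
    site_id = sprintf("d%03d", seq_len(n_demand)),
    x = runif(n_demand, 0, 5000), y = runif(n_demand, 0, 5000),
    population = runif(n_demand, 10, 1000)))
  sup <- supply_sites(data.frame(
    site_id = sprintf("s%02d", seq_len(n_supply)),
    x = runif(n_supply, 0, 5000), y = runif(n_supply, 0, 5000),
    supply_scale = runif(n_supply, 1, 100),
    weight = runif(n_supply, 0.5, 5)))
  cm <- cost_matrix(matrix(runif(n_demand * n_supply, 0, max_cost),
                           n_demand, n_supply),
                    mode = "test", metric = "time",
                    demand_ids = dem$site_id, supply_ids = sup$site_id)
  list(demand = dem, supply = sup, costs = cm)
}

# Literal double-loop transcription of the two floating catchment steps,
# independent of the vectorized engine. Returns ratios and accessibility.
fca_oracle <- function(demand, supply, costs, threshold,
                       kind = "gaussian", use_weights = TRUE) {
  g_fun <- function(t) {
    if (t > threshold) return(0)
    if (kind == "indicator") return(1)
    e0 <- exp(-0.5)
    (exp(-0.5 * (t / threshold)^2) - e0) / (1 - e0)
  }
  m <- unclass(costs)[demand$site_id, supply$site_id, drop = FALSE]
  R <- numeric(nrow(supply))
  for (j in seq_len(nrow(supply))) {
    denom <- 0
    for (i in seq_len(nrow(demand))) {
      if (m[i, j] <= threshold) {
        denom <- denom + demand$population[i] * g_fun(m[i, j])
      }
    }
    num <- supply$supply_scale[j] * (if (use_weights) supply$weight[j] else 1)
    R[j] <- if (denom == 0) 0 else num / denom
  }
  A <- numeric(nrow(demand))
  for (i in seq_len(nrow(demand))) {
    for (j in seq_len(nrow(supply))) {
      if (m[i, j] <= threshold) {
        A[i] <- A[i] + R[j] * g_fun(m[i, j])
      }
    }
  }
  list(ratios = setNames(R, supply$site_id),
       values = setNames(A, demand$site_id))
}

# Textbook-formula global Moran oracle on a dense weight matrix.
moran_oracle <- function(values, wmat) {
  z <- values - mean(values)
  n <- length(z)
  s0 <- sum(wmat)
  (n / s0) * as.numeric(t(z) %*% wmat %*% z) / sum(z^2)
}

# Dense weight matrix from a spatial_weights object (for oracles only).
weights_dense <- function(w) {
  n <- length(w$ids)
  m <- matrix(0, n, n, dimnames = list(w$ids, w$ids))
  for (i in seq_len(n)) m[i, w$neighbors[[i]]] <- w$weights[[i]]
  m
}
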