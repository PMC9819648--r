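#' Supply-demand ratios (first floating catchment step)
#'
#' For each supply site \eqn{j}, the decay-weighted population within its
#' catchment is accumulated and the ratio
#' \deqn{R_j = \frac{S_j W_j}{\sum_{i: t_{ij} \le t_0} D_i\, G(t_{ij})}}
#' is formed. With `use_weights = FALSE`, \eqn{W_j \equiv 1} and the ratio is
#' the plain (G)2SFCA supply-demand ratio. A supply site whose decay-weighted
#' demand is zero — an empty catchment, or only zero-population sites in reach
#' — gets \eqn{R_j = 0} with a warning, so isolated facilities contribute
#' nothing rather than aborting the run.
#'
#' @param demand A [demand_sites()] table.
#' @param supply A [supply_sites()] table.
#' @param costs A [cost_matrix()] whose dimnames match the site ids.
#' @param decay A [decay_spec()].
#' @param use_weights Multiply capacity by the quality weight \eqn{W_j}?
#' @return Named numeric vector of ratios, one per supply site (sorted id
#'   order).
#' @export
supply_demand_ratios <- function(demand, supply, costs, decay,
                                 use_weights = TRUE) {
  al <- align_costs(demand, supply, costs)
  g <- decay_eval(decay, al$cost)
  denom <- as.vector(crossprod(g, demand$population)) # sum_i D_i G(t_ij)
  num <- supply$supply_scale * (if (use_weights) supply$weight else 1)
  empty <- denom == 0
  if (any(empty)) {
    warning(sprintf(
      "%d supply site(s) with empty catchment (no decay-weighted demand): %s; R_j set to 0",
      sum(empty), paste(supply$site_id[empty], collapse = ", ")),
      call. = FALSE)
  }
  r <- ifelse(empty, 0, num / ifelse(empty, 1, denom))
  names(r) <- supply$site_id
  r
}

#' Accessibility field for one mode (second floating catchment step)
#'
#' Sums each reachable facility's supply-demand ratio, decay-weighted, at
#' every demand site:
#' \deqn{A_i = \sum_{j: t_{ij} \le t_0} R_j\, G(t_{ij}).}
#' A demand site with no facility inside its catchment gets exactly 0 — it
#' cannot obtain services within the travel-time threshold.
#'
#' @inheritParams supply_demand_ratios
#' @return An `accessibility_field`: list with `values` (named numeric per
#'   demand site), `ratios` (named numeric per supply site) and `mode`.
#' @export
accessibility <- function(demand, supply, costs, decay, use_weights = TRUE) {
  r <- supply_demand_ratios(demand, supply, costs, decay, use_weights)
  al <- align_costs(demand, supply, costs)
  g <- decay_eval(decay, al$cost)
  a <- as.vector(g %*% r)
  names(a) <- demand$site_id
  accessibility_field(a, ratios = r, mode = attr(costs, "mode"))
}

accessibility_field <- function(values, ratios = NULL, mode = NA_character_) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  structure(list(values = values, ratios = ratios, mode = mode),
            class = "accessibility_field")
}

#' @export
print.accessibility_field <- function(x, ...) {
  v <- x$values
  cat(sprintf("<accessibility_field> mode=%s sites=%d zero=%d\n",
              x$mode, length(v), sum(v == 0)))
  cat(sprintf("  min=%.4g median=%.4g max=%.4g\n",
              min(v), stats::median(v), max(v)))
  invisible(x)
}

#' @export
as.data.frame.accessibility_field <- function(x, ...) {
  data.frame(site_id = names(x$values), mode = x$mode,
             value = unname(x$values), stringsAsFactors = FALSE)
}

#' Composite accessibility across travel modes
#'
#' Convex combination of per-mode accessibility fields using the daily
#' travel-mode shares: \eqn{A_i = \sum_n W_{M_n} A_{i,M_n}}. Every per-mode
#' field must cover the same demand sites, and every mode in the mix must have
#' a field.
#'
#' @param fields Named list of `accessibility_field`s, one per mode; names (or
#'   field `mode` labels) must match the mix's modes.
#' @param mix A [mode_mix()].
#' @return An `accessibility_field` with `mode = "combined"`; its `ratios`
#'   element is a named list of the per-mode ratio vectors.
#' @export
combine_modes <- function(fields, mix) {
  stopifnot(inherits(mix, "mode_mix"))
  if (is.null(names(fields)) || any(!nzchar(names(fields)))) {
    names(fields) <- vapply(fields, function(f) f$mode, character(1))
  }
  miss <- setdiff(mix$modes, names(fields))
  if (length(miss)) {
    stop(sprintf("no accessibility field for mode(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ids <- names(fields[[mix$modes[1]]]$values)
  vals <- numeric(length(ids))
  names(vals) <- ids
  for (n in seq_along(mix$modes)) {
    f <- fields[[mix$modes[n]]]
    if (!identical(names(f$values), ids)) {
      stop("per-mode fields cover different demand sites", call. = FALSE)
    }
    vals <- vals + mix$shares[n] * f$values
  }
  accessibility_field(vals,
                      ratios = lapply(fields[mix$modes], `[[`, "ratios"),
                      mode = "combined")
}

#' Supply-competition multimodal G2SFCA pipeline
#'
#' Runs the two floating catchment steps independently for every travel mode
#' (each with its own travel-time matrix), then composites the per-mode fields
#' by the daily mode shares. This is the full model: Gaussian decay inside a
#' fixed travel-time threshold, facility capacity weighted by a quality score,
#' and a mode-share-weighted combination.
#'
#' @param demand,supply Site tables.
#' @param costs Named list of [cost_matrix()] objects, one per mode in `mix`.
#' @param decay A [decay_spec()]; the same kernel is used in both steps.
#' @param mix A [mode_mix()].
#' @param use_weights Use the quality weights \eqn{W_j}? Default `TRUE`.
#' @return List with `per_mode` (named list of fields, each retaining its
#'   per-mode ratios \eqn{R_{j,M_n}}) and `combined`.
#' @examples
#' dem <- demand_sites(data.frame(site_id = c("r1", "r2"), x = c(0, 1000),
#'                                y = 0, population = c(500, 800)))
#' sup <- supply_sites(data.frame(site_id = "p1", x = 500, y = 0,
#'                                supply_scale = 40000, weight = 4.5))
#' cm <- cost_matrix(matrix(c(10, 12), 2, 1), mode = "walking",
#'                   demand_ids = dem$site_id, supply_ids = sup$site_id)
#' run_scm_g2sfca(dem, sup, list(walking = cm), decay_spec("gaussian", 39),
#'                mode_mix("walking", 1))$combined
#' @export
run_scm_g2sfca <- function(demand, supply, costs, decay, mix,
                           use_weights = TRUE) {
  stopifnot(inherits(mix, "mode_mix"))
  miss <- setdiff(mix$modes, names(costs))
  if (length(miss)) {
    stop(sprintf("missing cost matrix for mode(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  fields <- lapply(mix$modes, function(m) {
    f <- accessibility(demand, supply, costs[[m]], decay, use_weights)
    f$mode <- m
    f
  })
  names(fields) <- mix$modes
  list(per_mode = fields, combined = combine_modes(fields, mix))
}

# Align a cost matrix to the canonical (sorted-id) site order, erroring on any
# id or dimension mismatch.
align_costs <- function(demand, supply, costs) {
  stopifnot(inherits(demand, "demand_sites"), inherits(supply, "supply_sites"))
  if (!inherits(costs, "cost_matrix")) {
    stop("`costs` must be a cost_matrix", call. = FALSE)
  }
  if (nrow(costs) != nrow(demand) || ncol(costs) != nrow(supply)) {
    stop(sprintf("cost matrix is %dx%d but there are %d demand and %d supply sites",
                 nrow(costs), ncol(costs), nrow(demand), nrow(supply)),
         call. = FALSE)
  }
  if (!setequal(rownames(costs), demand$site_id) ||
      !setequal(colnames(costs), supply$site_id)) {
    stop("cost matrix dimnames do not match site ids", call. = FALSE)
  }
  m <- unclass(costs)[demand$site_id, supply$site_id, drop = FALSE]
  list(cost = m)
}
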