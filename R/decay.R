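#' Gaussian travel-cost decay
#'
#' Normalized Gaussian distance/time-decay kernel used by the G2SFCA family.
#' Within the catchment threshold \eqn{t_0} the kernel is
#' \deqn{G(t) = \frac{e^{-\frac{1}{2}(t/t_0)^2} - e^{-1/2}}{1 - e^{-1/2}},}
#' which equals 1 at zero cost and falls continuously to exactly 0 at
#' \eqn{t = t_0}; beyond the threshold it is identically 0. Unreachable pairs
#' may be encoded as `Inf` and decay to 0.
#'
#' @param cost Nonnegative travel cost (minutes, or distance for a Euclidean
#'   baseline). Vectorized. `Inf` is the unreachable sentinel; `NA`/`NaN` are
#'   rejected.
#' @param threshold Positive catchment threshold in the same unit as `cost`.
#' @return Numeric vector in `[0, 1]`, same length as `cost`.
#' @seealso [indicator_decay()], [decay_spec()]
#' @examples
#' gaussian_decay(c(0, 19.5, 39, 60), threshold = 39)
#' @export
gaussian_decay <- function(cost, threshold) {
  check_threshold(threshold)
  check_cost(cost)
  inside <- cost <= threshold
  g <- numeric(length(cost))
  e0 <- exp(-0.5)
  g[inside] <- (exp(-0.5 * (cost[inside] / threshold)^2) - e0) / (1 - e0)
  # clamp tiny negative round-off at the boundary
  g[g < 0] <- 0
  g
}

#' Indicator (all-or-nothing) catchment decay
#'
#' Binary catchment membership of the classic 2SFCA method: 1 when the cost is
#' within the threshold (inclusive), 0 beyond it.
#'
#' @inheritParams gaussian_decay
#' @return Numeric vector of 0/1 values.
#' @export
indicator_decay <- function(cost, threshold) {
  check_threshold(threshold)
  check_cost(cost)
  as.numeric(cost <= threshold)
}

#' Decay specification
#'
#' Bundles the decay kind and the catchment threshold so that both floating
#' catchment steps use the same kernel.
#'
#' @param kind `"gaussian"` or `"indicator"`.
#' @param threshold Positive catchment threshold (minutes for travel-time
#'   matrices, planar units for the Euclidean baseline). Defaults to 39
#'   minutes, the average urban daily travel time used as catchment radius.
#' @return An object of class `decay_spec`.
#' @export
decay_spec <- function(kind = c("gaussian", "indicator"), threshold = 39) {
  kind <- match.arg(kind)
  check_threshold(threshold)
  structure(list(kind = kind, threshold = threshold), class = "decay_spec")
}

#' @export
print.decay_spec <- function(x, ...) {
  cat(sprintf("<decay_spec> kind=%s threshold=%g\n", x$kind, x$threshold))
  invisible(x)
}

# Evaluate a decay_spec on a vector or matrix of costs (shape preserved).
decay_eval <- function(decay, cost) {
  stopifnot(inherits(decay, "decay_spec"))
  g <- switch(decay$kind,
    gaussian  = gaussian_decay(as.vector(cost), decay$threshold),
    indicator = indicator_decay(as.vector(cost), decay$threshold)
  )
  if (is.matrix(cost)) {
    dim(g) <- dim(cost)
    dimnames(g) <- dimnames(cost)
  }
  g
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0) {
    stop("`threshold` must be a single positive finite number", call. = FALSE)
  }
  invisible(threshold)
}

check_cost <- function(cost) {
  if (!is.numeric(cost)) stop("`cost` must be numeric", call. = FALSE)
  if (anyNA(cost)) stop("`cost` contains NA/NaN", call. = FALSE)
  # Inf is the unreachable sentinel and is allowed; -Inf and negatives are not
  if (any(cost < 0)) stop("`cost` must be nonnegative", call. = FALSE)
  invisible(cost)
}
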