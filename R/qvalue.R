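#' Storey-Tibshirani q-values
#'
#' False-discovery-rate adjustment of a vector of p-values. The proportion
#' of true nulls pi0 is estimated on a lambda grid with the cubic-spline
#' smoother evaluated at the largest lambda; for short p-value vectors
#' (fewer than 50 tests), where the smoother is unstable, the single-point
#' estimate at lambda = 0.5 is used instead. Either estimate is floored at
#' 1/m (at least one null) and capped at 1. Q-values are
#' `q_i = pi0 * min_{p_j >= p_i} (m * p_j / rank_j)`, monotone in p and
#' clipped to [0, 1].
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param lambda Grid for pi0 estimation (default `seq(0.05, 0.95, 0.05)`).
#' @return List with `qvalues` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) return(list(qvalues = numeric(0), pi0 = NA_real_))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m < 50) {
    pi0 <- mean(p > 0.5) / 0.5
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  }
  pi0 <- min(1, max(pi0, 1 / m))
  ord <- order(p, decreasing = TRUE)
  q_ord <- pi0 * m * p[ord] / rank(p, ties.method = "max")[ord]
  q_ord <- cummin(pmin(q_ord, 1))
  q <- numeric(m)
  q[ord] <- q_ord
  list(qvalues = q, pi0 = pi0)
}
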