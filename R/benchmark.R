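# Simulation benchmark harness: power, type-I error, and exact-path
# recovery on pathway fixtures. Each grid cell is seeded independently from
# the base seed so results are reproducible bit-for-bit regardless of which
# cells are run.

cell_seed <- function(seed, index) (seed + 7919L * index) %% .Machine$integer.max

# One simulated dataset -> rotation p-values for several statistics that
# share the rotation draws (mirrors analysing one dataset with many
# methods).
simulated_pvalues <- function(fixture, mu, sigma2_g, n, n_rotations, stat_fns,
                              include_observed = TRUE) {
  study <- simulate_study(fixture, mu, sigma2_g, n)
  Y <- study$values
  E_obs <- matrix(rowMeans(Y), ncol = 1L, dimnames = list(rownames(Y), NULL))
  W <- rotation_weights(n, n_rotations)[[1L]]
  E_rot <- Y %*% W
  rownames(E_rot) <- rownames(Y)
  vapply(stat_fns, function(fn) {
    obs <- fn(E_obs)[1L]
    nulls <- fn(E_rot)
    k <- sum(nulls >= obs)
    if (include_observed) (1 + k) / (n_rotations + 1) else k / n_rotations
  }, 0)
}

#' Power experiment over a simulation grid
#'
#' For every combination of fixture, pathway effect `mu`, per-protein
#' variance `sigma2_g`, and sample size `n`, simulates `replicates`
#' datasets, computes rotation p-values for each requested method, and
#' reports the empirical power: the fraction of replicates with
#' `p <= alpha`. Each cell carries its binomial Monte-Carlo standard error.
#'
#' @param fixtures List of `pathway_fixture`s (e.g. [fixture_registry()]).
#' @param mu,sigma2_g,n Numeric vectors spanning the grid.
#' @param replicates Simulated datasets per cell (default 1000).
#' @param n_rotations Rotations per dataset (default 1000).
#' @param alpha Nominal significance level (default 0.05).
#' @param methods Statistic kinds (see [statistic_function()]).
#' @param seed Base seed; every cell derives its own stream from it.
#' @return Long-format data frame: fixture, method, mu, sigma2_g, n,
#'   power, se, replicates.
#' @export
run_power_experiment <- function(fixtures, mu = c(0.25, 0.5, 1), sigma2_g = 0,
                                 n = 10, replicates = 1000,
                                 n_rotations = 1000, alpha = 0.05,
                                 methods = "deap", seed = 1) {
  grid <- expand.grid(fixture = names(fixtures), mu = mu,
                      sigma2_g = sigma2_g, n = n,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fx <- fixtures[[grid$fixture[i]]]
    stat_fns <- lapply(methods, statistic_function, graph = fx$graph)
    names(stat_fns) <- methods
    set.seed(cell_seed(seed, i))
    reject <- matrix(FALSE, length(methods), replicates,
                     dimnames = list(methods, NULL))
    for (r in seq_len(replicates)) {
      p <- simulated_pvalues(fx, grid$mu[i], grid$sigma2_g[i], grid$n[i],
                             n_rotations, stat_fns)
      reject[, r] <- p <= alpha
    }
    pow <- rowMeans(reject)
    rows[[i]] <- data.frame(
      fixture = grid$fixture[i], method = methods, mu = grid$mu[i],
      sigma2_g = grid$sigma2_g[i], n = grid$n[i], power = unname(pow),
      se = unname(sqrt(pow * (1 - pow) / replicates)),
      replicates = replicates, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type-I error experiment
#'
#' Simulates data under the null model (`mu = 0`, `sigma2_g = 0`) and
#' reports the empirical rejection rate at each nominal level.
#'
#' @param fixtures List of `pathway_fixture`s.
#' @param replicates Null datasets per fixture (default 1000).
#' @param n Sample size (default 10).
#' @param n_rotations Rotations per dataset.
#' @param alphas Nominal levels (default 0.01, 0.05, 0.10).
#' @param methods Statistic kinds.
#' @param seed Base seed.
#' @return Data frame: fixture, method, alpha, rate, se, replicates.
#' @export
run_type1_experiment <- function(fixtures, replicates = 1000, n = 10,
                                 n_rotations = 1000,
                                 alphas = c(0.01, 0.05, 0.10),
                                 methods = "deap", seed = 1) {
  rows <- vector("list", 0L)
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    stat_fns <- lapply(methods, statistic_function, graph = fx$graph)
    names(stat_fns) <- methods
    set.seed(cell_seed(seed, i))
    pvals <- matrix(NA_real_, length(methods), replicates,
                    dimnames = list(methods, NULL))
    for (r in seq_len(replicates))
      pvals[, r] <- simulated_pvalues(fx, 0, 0, n, n_rotations, stat_fns)
    for (m in methods) {
      rate <- vapply(alphas, function(a) mean(pvals[m, ] <= a), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        fixture = fx$name, method = m, alpha = alphas, rate = rate,
        se = sqrt(rate * (1 - rate) / replicates),
        replicates = replicates, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact-path recovery experiment
#'
#' For each fixture with a designated true path, simulates datasets and
#' measures how often the reported best path's node set equals the true
#' path's node set exactly. Recovery is a property of the score and its
#' path reconstruction alone, so no rotations are involved.
#'
#' @param fixtures List of `pathway_fixture`s carrying `true_path`.
#' @param mu Pathway effect (single value).
#' @param sigma2_g Per-protein variance (default 0).
#' @param n Sample size (default 10).
#' @param replicates Datasets per fixture (default 1000).
#' @param seed Base seed.
#' @return Data frame with one row per fixture (fixture, mu, sigma2_g, n,
#'   replicates, recovered, recovery) plus a final `"pooled"` row
#'   aggregating across fixtures.
#' @export
run_path_recovery <- function(fixtures, mu, sigma2_g = 0, n = 10,
                              replicates = 1000, seed = 1) {
  fixtures <- Filter(function(f) !is.null(f$true_path), fixtures)
  if (!length(fixtures)) stop("no fixture carries a designated true path")
  rows <- vector("list", length(fixtures))
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    truth <- unique(fx$true_path)
    set.seed(cell_seed(seed, i))
    hit <- logical(replicates)
    for (r in seq_len(replicates)) {
      study <- simulate_study(fx, mu, sigma2_g, n)
      sc <- deap_score(fx$graph, expression_summary(study))
      hit[r] <- setequal(unique(sc$path), truth)
    }
    rows[[i]] <- data.frame(fixture = fx$name, mu = mu, sigma2_g = sigma2_g,
                            n = n, replicates = replicates,
                            recovered = sum(hit), recovery = mean(hit),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  pooled <- data.frame(fixture = "pooled", mu = mu, sigma2_g = sigma2_g,
                       n = n, replicates = sum(out$replicates),
                       recovered = sum(out$recovered),
                       recovery = sum(out$recovered) / sum(out$replicates),
                       stringsAsFactors = FALSE)
  out <- rbind(out, pooled)
  rownames(out) <- NULL
  out
}

#' Base-graphics power curves
#'
#' Plots power against one grid variable, one line per fixture/method
#' combination, with 2-SE error bars.
#'
#' @param results Data frame from [run_power_experiment()].
#' @param x Grid variable on the x-axis: `"mu"`, `"sigma2_g"`, or `"n"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `results`, invisibly.
#' @export
plot_power_curves <- function(results, x = "mu", ...) {
  stopifnot(x %in% c("mu", "sigma2_g", "n"))
  combos <- unique(results[c("fixture", "method")])
  xs <- sort(unique(results[[x]]))
  mat <- sapply(seq_len(nrow(combos)), function(i) {
    sub <- results[results$fixture == combos$fixture[i] &
                   results$method == combos$method[i], ]
    sub$power[match(xs, sub[[x]])]
  })
  graphics::matplot(xs, mat, type = "b", pch = 19, lty = 1,
                    xlab = x, ylab = "power", ylim = c(0, 1), ...)
  graphics::legend("bottomright", cex = 0.7, lty = 1,
                   col = seq_len(nrow(combos)),
                   legend = paste(combos$fixture, combos$method, sep = " / "))
  invisible(results)
}
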