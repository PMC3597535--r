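#' Draw a random rotation matrix
#'
#' Generates a Haar-distributed orthogonal matrix by QR decomposition of a
#' matrix of standard normal variates. The raw QR factor is not uniformly
#' distributed; the R-diagonal signs are fixed (made positive) so the
#' resulting Q is Haar on the orthogonal group.
#'
#' @param dim Dimension (>= 1).
#' @return A `dim` x `dim` orthogonal matrix.
#' @export
random_rotation <- function(dim) {
  if (dim < 1) stop("rotation dimension must be >= 1")
  X <- matrix(stats::rnorm(dim * dim), dim, dim)
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  d <- sign(diag(qr.R(qrX)))
  d[d == 0] <- 1
  Q * rep(d, each = dim)
}

#' Rotate an expression study
#'
#' Applies one shared rotation to every protein's sample vector, preserving
#' inter-protein correlation. When a nuisance design is supplied (overall
#' mean, covariates, blocking factors), the data are first projected onto
#' the residual space of the nuisance linear model, rotated there, mapped
#' back, and the fitted nuisance component is re-added; with no nuisance
#' terms the raw sample vectors are rotated directly, which is the correct
#' null for the paired one-sample test of zero mean log-ratio.
#'
#' @param study An [expression_study].
#' @param Q Orthogonal matrix from [random_rotation()]: `n x n` with no
#'   nuisance, `(n - q) x (n - q)` with a rank-`q` nuisance design.
#' @param nuisance Optional `n x q` numeric design matrix of nuisance terms
#'   (must have full column rank).
#' @return A new [expression_study] with rotated values.
#' @export
rotate_study <- function(study, Q, nuisance = NULL) {
  stopifnot(inherits(study, "expression_study"))
  Y <- study$values
  n <- ncol(Y)
  if (is.null(nuisance)) {
    if (!all(dim(Q) == c(n, n)))
      stop("Q must be ", n, " x ", n, " for a design without nuisance terms")
    Yr <- Y %*% t(Q)
  } else {
    nuisance <- as.matrix(nuisance)
    q <- ncol(nuisance)
    if (nrow(nuisance) != n) stop("nuisance design must have one row per sample")
    if (qr(nuisance)$rank < q) stop("nuisance design is rank deficient")
    if (!all(dim(Q) == c(n - q, n - q)))
      stop("Q must be ", n - q, " x ", n - q, " given ", q, " nuisance columns")
    qrN <- qr(nuisance)
    Qfull <- qr.Q(qrN, complete = TRUE)
    U <- Qfull[, seq_len(q), drop = FALSE]        # nuisance column space
    V <- Qfull[, -seq_len(q), drop = FALSE]       # residual space basis
    fitted <- (Y %*% U) %*% t(U)
    Z <- Y %*% V
    Yr <- fitted + (Z %*% t(Q)) %*% t(V)
  }
  dimnames(Yr) <- dimnames(Y)
  out <- study
  out$values <- Yr
  out
}

# Rotation weight vectors for sample-mean summaries.
#
# Summaries used here depend on the data only through weighted sample
# means Y %*% t, and rowMeans(Y %*% t(Q)) == Y %*% (t(Q) %*% t), so a
# rotation's effect on the summary is fully captured by an n-vector; R of
# them give all rotated summaries in one matrix product, exactly equal to
# rotating the full matrix and re-summarising. `targets` may have several
# columns (e.g. case- and control-mean weights); they share each rotation.
# With a nuisance design the rotation acts in the residual basis and the
# fitted nuisance component is re-added.
rotation_weights <- function(n, n_rotations, nuisance = NULL,
                             targets = matrix(1 / n, n, 1)) {
  targets <- as.matrix(targets)
  k <- ncol(targets)
  Ws <- replicate(k, matrix(NA_real_, n, n_rotations), simplify = FALSE)
  if (is.null(nuisance)) {
    for (j in seq_len(n_rotations)) {
      tq <- crossprod(random_rotation(n), targets)
      for (i in seq_len(k)) Ws[[i]][, j] <- tq[, i]
    }
  } else {
    nuisance <- as.matrix(nuisance)
    q <- ncol(nuisance)
    if (nrow(nuisance) != n) stop("nuisance design must have one row per sample")
    qrN <- qr(nuisance)
    if (qrN$rank < q) stop("nuisance design is rank deficient")
    Qfull <- qr.Q(qrN, complete = TRUE)
    U <- Qfull[, seq_len(q), drop = FALSE]
    V <- Qfull[, -seq_len(q), drop = FALSE]
    base <- U %*% crossprod(U, targets)   # fitted nuisance part, fixed
    Vt <- crossprod(V, targets)
    for (j in seq_len(n_rotations)) {
      tq <- base + V %*% crossprod(random_rotation(n - q), Vt)
      for (i in seq_len(k)) Ws[[i]][, j] <- tq[, i]
    }
  }
  Ws
}

#' Rotation-test p-value for one pathway
#'
#' Builds the null distribution of the pathway statistic by recomputing it
#' on `n_rotations` randomly rotated copies of the study and returns the
#' Monte-Carlo p-value. By default the add-one estimator
#' `p = (1 + #\{s_i >= s*\}) / (R + 1)` is used, which never returns an
#' exact zero; `include_observed = FALSE` gives the plain proportion.
#'
#' @param graph A [pathway_graph].
#' @param study An [expression_study] (paired mode).
#' @param n_rotations Number of rotations R (>= 1, default 1000).
#' @param nuisance Optional nuisance design matrix (see [rotate_study()]).
#' @param statistic Function `(graph, E_mat) -> numeric vector` evaluating
#'   the pathway statistic for each summary column; defaults to
#'   [deap_score_matrix()].
#' @param include_observed Use the add-one p-value (default `TRUE`).
#' @return List with `p`, `observed` s*, and `null` (the R rotated
#'   statistics, all nonnegative).
#' @export
rotation_pvalue <- function(graph, study, n_rotations = 1000, nuisance = NULL,
                            statistic = deap_score_matrix,
                            include_observed = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (n_rotations < 1) stop("n_rotations must be >= 1")
  if (study$mode != "paired")
    stop("rotation testing is implemented for paired (log-ratio) studies; ",
         "summarise unpaired data to per-sample ratios first")
  Y <- study$values
  n <- ncol(Y)
  obs <- statistic(graph, matrix(rowMeans(Y), ncol = 1L,
                                 dimnames = list(rownames(Y), NULL)))
  W <- rotation_weights(n, n_rotations, nuisance)[[1L]]
  E_rot <- Y %*% W
  rownames(E_rot) <- rownames(Y)
  null_stats <- statistic(graph, E_rot)
  k <- sum(null_stats >= obs)
  p <- if (include_observed) (1 + k) / (n_rotations + 1) else k / n_rotations
  list(p = p, observed = obs, null = null_stats)
}
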