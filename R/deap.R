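#' Differential expression analysis for pathways
#'
#' Fits the pathway model to an expression study: for every pathway, finds
#' the maximally differentially expressed signed path (statistic s* =
#' maximum absolute clamped running sum over paths, with catalytic edges
#' adding and inhibitory edges subtracting downstream expression), assesses
#' its significance with a random-rotation test, and adjusts across
#' pathways with Storey-Tibshirani q-values. One shared rotation stream is
#' used for all pathways of the dataset, preserving their correlation, as
#' in permutation practice.
#'
#' @param expression Protein-by-sample numeric matrix with protein
#'   rownames, or the path to an expression TSV (see [read_expression()]).
#' @param pathways Named list of [pathway_graph]s, or the path to a pathway
#'   edge-list TSV (see [parse_pathway_table()]).
#' @param design Sample design data frame (or design TSV path) for unpaired
#'   mode; `NULL` for paired log-ratio data.
#' @param mode `"paired"` (columns are log-ratios) or `"unpaired"`
#'   (case/control columns per `design`). Defaults to paired when no design
#'   is given.
#' @param n_rotations Number R of random rotations (default 1000).
#' @param seed Optional integer seed for the rotation stream.
#' @param log_base Log base for the unpaired summary (default 2).
#' @param alpha Significance level recorded for summaries (default 0.05).
#' @param min_coverage Pathways with a smaller fraction of measured
#'   proteins are still scored but flagged (default 0, no flagging).
#' @return Object of class `deap` with components `results` (data frame:
#'   pathway_id, score, signed_score, path, p_value, q_value, coverage,
#'   sorted by q then p), `scores` (per-pathway [deap_score] objects),
#'   `null` (pathway x R matrix of rotated statistics), `pi0`, and
#'   `config`.
#' @examples
#' fx <- fixture_registry()
#' set.seed(1)
#' study <- simulate_study(fx$catalytic_string, mu = 1)
#' fit <- deap(study$values, list(catalytic_string = fx$catalytic_string$graph),
#'             n_rotations = 99, seed = 1)
#' fit
#' @export
deap <- function(expression, pathways, design = NULL,
                 mode = if (is.null(design)) "paired" else "unpaired",
                 n_rotations = 1000, seed = NULL, log_base = 2,
                 alpha = 0.05, min_coverage = 0) {
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(pathways)) pathways <- parse_pathway_table(pathways)
  if (is.character(design)) design <- read_design(design)
  if (inherits(pathways, "pathway_graph")) {
    pathways <- stats::setNames(list(pathways), pathways$pathway_id)
  }
  if (!length(pathways)) stop("no pathways supplied")
  mode <- match.arg(mode, c("paired", "unpaired"))
  study <- expression_study(expression, mode = mode, design = design,
                            log_base = log_base)
  expr_ids <- rownames(study$values)
  path_ids <- unique(unlist(lapply(pathways, pathway_proteins)))
  if (!any(path_ids %in% expr_ids))
    stop("no overlap between expression identifiers and pathway members.\n",
         "  expression ids look like: ",
         paste(utils::head(expr_ids, 3), collapse = ", "), "\n",
         "  pathway members look like: ",
         paste(utils::head(path_ids, 3), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(study$values)
  if (n_rotations < 1) stop("n_rotations must be >= 1")
  E_obs <- observed_summary_matrix(study)
  E_rot <- rotated_summary_matrix(study, n_rotations)
  null_mat <- matrix(NA_real_, length(pathways), n_rotations,
                     dimnames = list(names(pathways), NULL))
  scores <- vector("list", length(pathways))
  names(scores) <- names(pathways)
  rows <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    g <- pathways[[i]]
    sc <- deap_score(g, stats::setNames(E_obs[, 1L], rownames(E_obs)))
    nulls <- deap_score_matrix(g, E_rot)
    p <- (1 + sum(nulls >= sc$statistic)) / (n_rotations + 1)
    null_mat[i, ] <- nulls
    scores[[i]] <- sc
    rows[[i]] <- data.frame(
      pathway_id = names(pathways)[i],
      score = sc$statistic,
      signed_score = sc$signed_score,
      path = format_path(sc, g),
      p_value = p,
      q_value = NA_real_,
      coverage = sc$coverage,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  qv <- storey_qvalues(results$p_value)
  results$q_value <- qv$qvalues
  ord <- order(results$q_value, results$p_value, results$pathway_id)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  low_cov <- results$pathway_id[results$coverage < min_coverage]
  if (length(low_cov))
    warning("pathway(s) below the coverage threshold: ",
            paste(low_cov, collapse = ", "))
  structure(list(
    results = results,
    scores = scores,
    null = null_mat,
    pi0 = qv$pi0,
    config = list(mode = mode, n_rotations = n_rotations, seed = seed,
                  log_base = log_base, alpha = alpha,
                  n_samples = n, n_pathways = length(pathways)),
    call = match.call()
  ), class = "deap")
}

# Observed per-protein summary as a 1-column matrix.
observed_summary_matrix <- function(study) {
  E <- expression_summary(study)
  matrix(E, ncol = 1L, dimnames = list(names(E), NULL))
}

# Per-rotation summary columns via the linearity of group means: the
# summary depends on the data only through weighted sample means, so all R
# rotated summaries come from matrix products with rotation weight vectors
# (exactly equal to rotating the full matrix and re-summarising). Paired
# mode rotates the raw sample vectors (the null of interest is a zero mean
# log-ratio); unpaired mode rotates residuals about the per-protein mean
# (the overall mean is a nuisance) and re-adds the fitted component before
# taking the log group means.
rotated_summary_matrix <- function(study, n_rotations) {
  Y <- study$values
  n <- ncol(Y)
  if (study$mode == "paired") {
    W <- rotation_weights(n, n_rotations)[[1L]]
    E_rot <- Y %*% W
  } else {
    is_case <- study$design$condition == "case"
    targets <- cbind(case = ifelse(is_case, 1 / sum(is_case), 0),
                     control = ifelse(!is_case, 1 / sum(!is_case), 0))
    Ws <- rotation_weights(n, n_rotations, nuisance = matrix(1, n, 1),
                           targets = targets)
    MC <- Y %*% Ws[[1L]]
    M0 <- Y %*% Ws[[2L]]
    if (any(MC <= 0) || any(M0 <= 0))
      stop("rotation produced non-positive group means, so the log-scale ",
           "unpaired summary is undefined; pre-shift the data or supply ",
           "paired log-ratios")
    E_rot <- (log(MC) - log(M0)) / log(study$log_base)
  }
  rownames(E_rot) <- rownames(Y)
  E_rot
}

#' @export
print.deap <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Pathway differential expression fit: %d pathway(s), %d samples (%s mode), R = %d rotations\n",
              cfg$n_pathways, cfg$n_samples, cfg$mode, cfg$n_rotations))
  res <- x$results
  res$score <- round(res$score, 3)
  res$signed_score <- round(res$signed_score, 3)
  res$p_value <- signif(res$p_value, 3)
  res$q_value <- signif(res$q_value, 3)
  res$coverage <- round(res$coverage, 2)
  print(utils::head(res, 10), row.names = FALSE)
  if (nrow(res) > 10) cat("... and", nrow(res) - 10, "more pathways\n")
  invisible(x)
}

#' @export
summary.deap <- function(object, alpha = object$config$alpha, ...) {
  res <- object$results
  out <- list(
    n_pathways = nrow(res),
    alpha = alpha,
    n_significant_p = sum(res$p_value <= alpha),
    n_significant_q = sum(res$q_value <= alpha),
    pi0 = object$pi0,
    top = utils::head(res, 5)
  )
  class(out) <- "summary.deap"
  out
}

#' @export
print.summary.deap <- function(x, ...) {
  cat(sprintf("%d pathways tested; %d with p <= %.3g, %d with q <= %.3g (pi0 = %.3g)\n",
              x$n_pathways, x$n_significant_p, x$alpha, x$n_significant_q,
              x$alpha, x$pi0))
  cat("Top pathways:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.deap <- function(x, ...) x$results

#' Plot the rotation null of a fitted pathway
#'
#' Histogram of the rotated statistics for one pathway with the observed
#' statistic marked; the Monte-Carlo p-value is the fraction of the null
#' mass at or beyond the line.
#'
#' @param x A `deap` fit.
#' @param pathway Pathway id (default: the top-ranked pathway).
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.deap <- function(x, pathway = x$results$pathway_id[1L], ...) {
  nulls <- x$null[pathway, ]
  obs <- x$scores[[pathway]]$statistic
  graphics::hist(nulls, breaks = 30, col = "grey85", border = "white",
                 main = paste("Rotation null:", pathway),
                 xlab = "pathway statistic",
                 xlim = range(c(nulls, obs)) * c(1, 1.05), ...)
  graphics::abline(v = obs, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("observed s* = %.3g, p = %.3g", obs,
                          x$results$p_value[x$results$pathway_id == pathway]),
                  side = 3, line = 0, cex = 0.8)
  invisible(x)
}

#' Write fitted pathway results as tab-separated text
#'
#' One row per pathway (pathway_id, score, signed_score, path, p_value,
#' q_value, coverage), preceded by `#` provenance comments recording the
#' rotation count, seed, mode, and package version.
#'
#' @param fit A `deap` fit.
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_deap_results <- function(fit, file) {
  stopifnot(inherits(fit, "deap"))
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  cfg <- fit$config
  writeLines(c(
    sprintf("# deapr %s pathway results", as.character(utils::packageVersion("deapr"))),
    sprintf("# mode=%s rotations=%d seed=%s log_base=%g alpha=%g",
            cfg$mode, cfg$n_rotations,
            if (is.null(cfg$seed)) "NA" else as.character(cfg$seed),
            cfg$log_base, cfg$alpha)
  ), con)
  utils::write.table(fit$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
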