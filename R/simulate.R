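#' Load pathway fixtures from files
#'
#' A fixture binds a pathway graph to a per-protein on/off assignment `d`
#' (+1 up-regulated, -1 down-regulated, 0 unaffected) and, optionally, a
#' designated true differentially expressed path. This loader accepts the
#' same edge-list pathway format as [parse_pathway_table()], a tab-separated
#' effects table (`pathway_id`, `protein`, `d`), and an optional true-path
#' table (`pathway_id`, `true_path` as a semicolon-joined node-id chain),
#' so user-supplied scenarios (e.g. curated KEGG or Reactome topologies)
#' plug into the same machinery as the bundled fixtures.
#'
#' @param pathway_file Pathway edge-list TSV.
#' @param effects_file Effects TSV with columns pathway_id, protein, d.
#' @param true_path_file Optional true-path TSV.
#' @return Named list of `pathway_fixture` objects, each with `name`,
#'   `graph`, `d` (named vector over the pathway's proteins), and
#'   `true_path` (node-id chain, possibly NULL).
#' @export
load_fixtures <- function(pathway_file, effects_file, true_path_file = NULL) {
  graphs <- parse_pathway_table(pathway_file)
  eff <- utils::read.delim(effects_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "protein", "d") %in% names(eff)))
    stop("effects table must have columns pathway_id, protein, d")
  if (!all(eff$d %in% c(-1, 0, 1)))
    stop("d must be -1, 0, or +1")
  truth <- NULL
  if (!is.null(true_path_file)) {
    truth <- utils::read.delim(true_path_file, comment.char = "#",
                               stringsAsFactors = FALSE)
    if (!all(c("pathway_id", "true_path") %in% names(truth)))
      stop("true-path table must have columns pathway_id, true_path")
  }
  out <- list()
  for (pid in names(graphs)) {
    g <- graphs[[pid]]
    prot <- pathway_proteins(g)
    erows <- eff[eff$pathway_id == pid, , drop = FALSE]
    unknown <- setdiff(erows$protein, prot)
    if (length(unknown))
      stop("fixture '", pid, "': d assigned to unknown protein(s): ",
           paste(unknown, collapse = ", "))
    d <- stats::setNames(rep(0, length(prot)), prot)
    d[erows$protein] <- erows$d
    tp <- NULL
    if (!is.null(truth)) {
      trow <- truth[truth$pathway_id == pid, , drop = FALSE]
      if (nrow(trow)) {
        tp <- strsplit(trow$true_path[1L], ";", fixed = TRUE)[[1L]]
        missing_nodes <- setdiff(tp, names(g$nodes))
        if (length(missing_nodes))
          stop("fixture '", pid, "': true path references unknown node(s): ",
               paste(missing_nodes, collapse = ", "))
      }
    }
    out[[pid]] <- structure(list(name = pid, graph = g, d = d, true_path = tp),
                            class = "pathway_fixture")
  }
  out
}

#' The five bundled simulated pathway fixtures
#'
#' Returns the five pathway topologies used by the validation experiments:
#' a catalytic string and an inhibitory string (all five nodes 'on', the
#' inhibitory string alternating up/down so the regulation is coherent), a
#' branch point and a mixed-regulation pathway whose true path covers only
#' part of the graph, and a 14-protein long-alternate-route pathway whose
#' true differentially expressed path contains just 4 proteins. The
#' fixtures are stored as plain data files under `inst/extdata/fixtures`.
#'
#' @return Named list of 5 `pathway_fixture` objects.
#' @export
fixture_registry <- function() {
  dir <- system.file("extdata", "fixtures", package = "deapr", mustWork = TRUE)
  load_fixtures(file.path(dir, "simulated_pathways.tsv"),
                file.path(dir, "node_effects.tsv"),
                file.path(dir, "true_paths.tsv"))
}

#' @export
print.pathway_fixture <- function(x, ...) {
  cat(sprintf("<pathway_fixture> %s: %d nodes, %d on, true path %s\n",
              x$name, length(x$graph$nodes), sum(x$d != 0),
              if (is.null(x$true_path)) "unset"
              else paste(x$true_path, collapse = ";")))
  invisible(x)
}

#' Simulate expression data on a pathway fixture
#'
#' Draws a protein-by-sample matrix from the multivariate normal model
#' `value = d * (mu + g) + e`, where `d` is the fixture's per-protein
#' on/off indicator, `mu >= 0` is the pathway effect (mean absolute
#' expression of 'on' proteins), `g ~ N(0, sigma2_g)` is a per-protein
#' effect drawn once and shared across replicate samples, and
#' `e ~ N(0, 1)` is drawn per protein and sample. Values are treated as
#' paired log-ratios, so the per-protein summary is the row mean.
#'
#' @param fixture A `pathway_fixture` (or any list with `graph` and `d`).
#' @param mu Pathway effect, >= 0.
#' @param sigma2_g Per-protein effect variance, >= 0 (default 0).
#' @param n Number of replicate samples, >= 2 (default 10).
#' @return An [expression_study] in paired mode.
#' @export
simulate_study <- function(fixture, mu, sigma2_g = 0, n = 10) {
  stopifnot(mu >= 0, sigma2_g >= 0, n >= 2)
  d <- fixture$d
  p <- length(d)
  g <- stats::rnorm(p, 0, sqrt(sigma2_g))
  e <- matrix(stats::rnorm(p * n), p, n)
  values <- d * (mu + g) + e
  dimnames(values) <- list(names(d), sprintf("sample%02d", seq_len(n)))
  expression_study(values, mode = "paired")
}

#' Write one simulated replicate to disk
#'
#' Emits the standard expression TSV, a design TSV, and (when the fixture
#' carries one) a truth file listing the designed true path, so simulated
#' data flow through exactly the same input path as real studies.
#'
#' @param study An [expression_study].
#' @param fixture The generating `pathway_fixture`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_simulated_study <- function(study, fixture, dir, prefix = fixture$name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_file <- file.path(dir, paste0(prefix, "_expression.tsv"))
  design_file <- file.path(dir, paste0(prefix, "_design.tsv"))
  write_expression(study$values, expr_file)
  design <- data.frame(sample_id = colnames(study$values),
                       condition = "log_ratio", stringsAsFactors = FALSE)
  utils::write.table(design, design_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(expr_file, design_file)
  if (!is.null(fixture$true_path)) {
    truth_file <- file.path(dir, paste0(prefix, "_truth.txt"))
    writeLines(paste(fixture$true_path, collapse = ";"), truth_file)
    files <- c(files, truth_file)
  }
  invisible(files)
}
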