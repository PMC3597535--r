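#' Construct an expression study
#'
#' Bundles a protein-by-sample value matrix with its experimental design.
#' Two modes are supported, matching the two common layouts of expression
#' experiments:
#'
#' * `"paired"` (two-channel): every column is already a per-sample
#'   log-ratio between conditions; no design table is needed and the
#'   per-protein summary is the row mean.
#' * `"unpaired"` (single-channel): columns are individual samples labelled
#'   case or control in `design`; the per-protein summary is the difference
#'   of the logarithms of the arithmetic group means.
#'
#' @param values Numeric matrix, proteins in rows (rownames required),
#'   samples in columns.
#' @param mode `"paired"` or `"unpaired"`.
#' @param design For unpaired mode, a data frame with columns `sample_id`
#'   (matching `colnames(values)`) and `condition` (`"case"`/`"control"`);
#'   extra covariate columns are carried along.
#' @param log_base Logarithm base for the unpaired summary (default 2).
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, mode = c("paired", "unpaired"),
                             design = NULL, log_base = 2) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("expression matrix must have protein identifiers as rownames")
  storage.mode(values) <- "double"
  stopifnot(log_base > 0)
  if (mode == "unpaired") {
    if (is.null(design))
      stop("unpaired mode requires a design table (sample_id, condition)")
    design <- as.data.frame(design, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "condition") %in% names(design)))
      stop("design table must have columns sample_id and condition")
    if (!setequal(design$sample_id, colnames(values)))
      stop("design sample_ids do not match expression column names")
    design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
    if (!all(design$condition %in% c("case", "control")))
      stop("condition must be 'case' or 'control'")
    if (sum(design$condition == "case") < 1L ||
        sum(design$condition == "control") < 1L)
      stop("unpaired mode requires at least one case and one control sample")
  }
  structure(list(values = values, mode = mode, design = design,
                 log_base = log_base),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d proteins x %d samples, %s mode\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' Per-protein differential-expression summary E(x)
#'
#' Collapses an expression study to one signed value per protein: the mean
#' log-ratio in paired mode, or `log(mean(case)) - log(mean(control))` in
#' the configured base for unpaired mode. Unpaired data whose group means
#' are not strictly positive cannot be summarised on a log scale and raise
#' an error; shift the data or use paired mode.
#'
#' @param study An [expression_study].
#' @return Named numeric vector, one entry per protein.
#' @export
expression_summary <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (study$mode == "paired") {
    rowMeans(study$values)
  } else {
    case <- study$values[, study$design$condition == "case", drop = FALSE]
    ctrl <- study$values[, study$design$condition == "control", drop = FALSE]
    mc <- rowMeans(case)
    m0 <- rowMeans(ctrl)
    if (any(mc <= 0) || any(m0 <= 0))
      stop("unpaired summary undefined: some group means are not strictly ",
           "positive; pre-shift the data or use paired log-ratios")
    (log(mc) - log(m0)) / log(study$log_base)
  }
}

#' Node-level expression value
#'
#' Sums the summary values of a node's member proteins after collapsing
#' members with exactly equal values to a single contribution. Exact-equal
#' duplication within one node is interpreted as data duplication (the same
#' measurement attached to redundant identifiers, e.g. near-identical
#' protein variants quantified together) and is counted once. Members
#' missing from the summary contribute 0.
#'
#' @param members Character vector of protein identifiers in the node.
#' @param summary Named numeric vector from [expression_summary()].
#' @return Single numeric value.
#' @export
node_expression <- function(members, summary) {
  vals <- summary[members]
  vals <- vals[!is.na(vals)]
  sum(unique(vals))
}

# Node-by-m matrix of node expression values for all nodes of a graph.
# E_mat: proteins x m matrix (m summary columns, e.g. one per rotation).
# Missing proteins contribute 0. Duplicate collapse is applied per column.
node_value_matrix <- function(graph, E_mat) {
  if (is.null(dim(E_mat))) E_mat <- matrix(E_mat, ncol = 1L,
                                           dimnames = list(names(E_mat), NULL))
  node_ids <- names(graph$nodes)
  m <- ncol(E_mat)
  out <- matrix(0, nrow = length(node_ids), ncol = m,
                dimnames = list(node_ids, NULL))
  prot <- rownames(E_mat)
  for (i in seq_along(node_ids)) {
    mem <- graph$nodes[[i]]
    idx <- match(mem, prot)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    if (length(idx) == 1L) {
      out[i, ] <- E_mat[idx, ]
    } else {
      sub <- E_mat[idx, , drop = FALSE]
      out[i, ] <- apply(sub, 2L, function(v) sum(unique(v)))
    }
  }
  out
}

# Fraction of a pathway's proteins present in the summary (coverage
# diagnostic for missing-measurement logging).
pathway_coverage <- function(graph, summary) {
  prot <- pathway_proteins(graph)
  mean(prot %in% names(summary))
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and a first column of protein
#' identifiers.
#'
#' @param file Path or connection.
#' @return Numeric matrix with protein rownames.
#' @export
read_expression <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs an id column and >=1 sample")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate protein identifiers in expression table")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix as tab-separated text
#' @param values Numeric matrix with protein rownames.
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_expression <- function(values, file) {
  tab <- data.frame(protein = rownames(values), values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a sample design table
#'
#' Tab-separated with columns `sample_id` and `condition`; optional
#' `pair_id` and covariate columns are preserved.
#'
#' @param file Path or connection.
#' @return Data frame.
#' @export
read_design <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(tab)))
    stop("design table must have columns sample_id and condition")
  tab
}
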