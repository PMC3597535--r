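# Shared builders for test graphs and studies.

# Linear chain with given node ids and per-edge kinds.
chain_graph <- function(ids, kinds = "catalysis", pathway_id = "chain") {
  k <- length(ids) - 1L
  kinds <- rep_len(kinds, k)
  pathway_graph(
    pathway_id,
    nodes = stats::setNames(as.list(ids), ids),
    edges = data.frame(edge_id = sprintf("e%02d", seq_len(k)),
                       reactant = ids[-length(ids)], product = ids[-1L],
                       kind = kinds, stringsAsFactors = FALSE))
}

# Eight-node branching pathway with one inhibitory edge: two convergent
# cascades meeting at A7, plus a side branch to A8.
branching_graph8 <- function() {
  pathway_graph(
    "branching8",
    nodes = stats::setNames(as.list(paste0("A", 1:8)), paste0("A", 1:8)),
    edges = data.frame(
      edge_id = sprintf("e%d", 1:8),
      reactant = c("A3", "A1", "A4", "A2", "A5", "A3", "A6", "A6"),
      product  = c("A4", "A4", "A7", "A5", "A7", "A6", "A8", "A7"),
      kind = c("catalysis", "inhibition", rep("catalysis", 6)),
      stringsAsFactors = FALSE))
}

# Random DAG on n nodes: edges follow a topological order, random kinds.
random_dag <- function(n, p = runif(1, 0.15, 0.4)) {
  ids <- sprintf("N%02d", seq_len(n))
  rows <- list()
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < p) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          edge_id = sprintf("e%03d", k), reactant = ids[i], product = ids[j],
          kind = sample(c("catalysis", "inhibition"), 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!k)
    rows[[1L]] <- data.frame(edge_id = "e001", reactant = ids[1L],
                             product = ids[2L], kind = "catalysis",
                             stringsAsFactors = FALSE)
  pathway_graph("random_dag", stats::setNames(as.list(ids), ids),
                do.call(rbind, rows))
}

random_summary <- function(graph) {
  ids <- names(graph$nodes)
  stats::setNames(rnorm(length(ids)), ids)
}

# Independent path-count oracle: plain node-adjacency DFS counting simple
# paths (and simple cycles) of <= max_edges edges. Written against the node
# list, not the package's edge machinery.
dfs_count_paths <- function(graph, max_edges) {
  e <- graph$edges
  total <- 0L
  extend <- function(chain) {
    last <- chain[length(chain)]
    out_rows <- which(e$reactant == last)
    for (r in out_rows) {
      nxt <- e$product[r]
      if (nxt == chain[1L]) {
        total <<- total + 1L       # simple cycle closes; do not extend
      } else if (!(nxt %in% chain)) {
        total <<- total + 1L
        if (length(chain) < max_edges) extend(c(chain, nxt))
      }
    }
  }
  for (start in unique(e$reactant)) extend(start)
  total
}

pathway_tsv_text <- function(rows) {
  header <- "pathway_id\tedge_id\treactants\tproducts\tinteraction"
  paste(c(header, rows), collapse = "\n")
}

as_tsv_file <- function(text) {
  f <- tempfile(fileext = ".tsv")
  writeLines(text, f)
  f
}
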