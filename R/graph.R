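#' Construct a pathway graph
#'
#' A pathway is a directed graph whose nodes are sets of protein identifiers
#' and whose edges carry a regulatory type: `"catalysis"` (the reactant node
#' promotes the product node, multiplier +1) or `"inhibition"` (the reactant
#' represses the product, multiplier -1). Node identity is the sorted,
#' semicolon-joined member list, so reactions sharing a protein set share a
#' node. Bidirectional relations are encoded as two opposed directed edges.
#'
#' @param pathway_id Single string naming the pathway.
#' @param nodes Named list: node id -> character vector of protein members
#'   (each non-empty).
#' @param edges Data frame with columns `edge_id`, `reactant`, `product`,
#'   `kind` (`"catalysis"` or `"inhibition"`). `reactant`/`product` must
#'   reference names of `nodes`.
#' @return An object of class `pathway_graph`: a list with the validated
#'   `pathway_id`, `nodes`, `edges` (sorted by `edge_id`, with a derived
#'   integer `multiplier` column in {+1, -1}), and a `children` adjacency
#'   index mapping each edge to the edges leaving its product node.
#' @export
pathway_graph <- function(pathway_id, nodes, edges) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  if (length(nodes) == 0L)
    stop("pathway '", pathway_id, "': at least one node is required")
  if (is.null(names(nodes)) || anyDuplicated(names(nodes)))
    stop("pathway '", pathway_id, "': node ids must be unique and named")
  for (id in names(nodes)) {
    mem <- nodes[[id]]
    if (!is.character(mem) || length(mem) == 0L || any(!nzchar(mem)))
      stop("pathway '", pathway_id, "': node '", id,
           "' must have a non-empty character member set")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("edge_id", "reactant", "product", "kind")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols))
    stop("edge table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(edges)) {
    if (anyDuplicated(edges$edge_id))
      stop("pathway '", pathway_id, "': duplicate edge_id")
    bad_kind <- setdiff(unique(edges$kind), c("catalysis", "inhibition"))
    if (length(bad_kind))
      stop("pathway '", pathway_id, "': unknown edge kind: ",
           paste(bad_kind, collapse = ", "))
    unknown <- setdiff(unique(c(edges$reactant, edges$product)), names(nodes))
    if (length(unknown))
      stop("pathway '", pathway_id, "': edge references unknown node(s): ",
           paste(unknown, collapse = ", "))
    # Parallel edges with identical (reactant, product, kind) collapse to one;
    # opposed kinds on the same node pair are kept as distinct edges.
    key <- paste(edges$reactant, edges$product, edges$kind, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[order(edges$edge_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges$multiplier <- ifelse(edges$kind == "catalysis", 1L, -1L)
  g <- structure(
    list(pathway_id = pathway_id, nodes = nodes, edges = edges,
         children = NULL),
    class = "pathway_graph"
  )
  g$children <- build_adjacency(g)
  g
}

#' Rebuild the edge adjacency index of a pathway graph
#'
#' For each edge, lists (as integer row indices into `graph$edges`, in
#' `edge_id` order) the edges whose reactant node equals that edge's product
#' node. This index drives the scoring recursion; it can be rebuilt at any
#' time to check consistency with the edge table.
#'
#' @param graph A `pathway_graph`.
#' @return List of integer vectors, one per edge.
#' @export
build_adjacency <- function(graph) {
  edges <- graph$edges
  if (!nrow(edges)) return(list())
  out_of <- split(seq_len(nrow(edges)), edges$reactant)
  lapply(edges$product, function(p) {
    kids <- out_of[[p]]
    if (is.null(kids)) integer(0) else sort(kids)
  })
}

#' @export
print.pathway_graph <- function(x, ...) {
  n_inh <- sum(x$edges$kind == "inhibition")
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges (%d inhibitory)\n",
              x$pathway_id, length(x$nodes), nrow(x$edges), n_inh))
  invisible(x)
}

#' List the leaf (root-level) edges of a pathway graph
#'
#' A leaf edge has no upstream edge pointing into its reactant node; these
#' edges seed the scoring recursion. In a graph made entirely of cycles there
#' may be none.
#'
#' @param graph A `pathway_graph`.
#' @return Integer vector of edge row indices, in `edge_id` order.
#' @export
leaf_edges <- function(graph) {
  edges <- graph$edges
  if (!nrow(edges)) return(integer(0))
  has_upstream <- edges$reactant %in% edges$product
  which(!has_upstream)
}

#' All protein identifiers mentioned by a pathway graph
#' @param graph A `pathway_graph`.
#' @return Sorted character vector of unique member proteins.
#' @export
pathway_proteins <- function(graph) {
  sort(unique(unlist(graph$nodes, use.names = FALSE)))
}

# Canonical node id for a protein member set: sorted, semicolon-joined.
node_id_for <- function(members) paste(sort(unique(members)), collapse = ";")
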