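#' Enumerate simple paths and simple cycles of a pathway graph
#'
#' A path is an ordered list of edges in which each edge's reactant node is
#' the previous edge's product node, with no repeated nodes except that the
#' final product may close the path back at its first node (a simple cycle).
#' Enumeration is exhaustive up to `max_edges` edges and deterministic:
#' paths are produced in lexicographic order of their `edge_id` sequences.
#'
#' @param graph A [pathway_graph].
#' @param max_edges Maximum number of edges per path (>= 1).
#' @return List of paths; each is a list with `edge_idx` (integer rows into
#'   `graph$edges`), `nodes` (the node-id chain, length edges + 1), and
#'   `is_cycle`.
#' @export
enumerate_paths <- function(graph, max_edges) {
  stopifnot(max_edges >= 1)
  edges <- graph$edges
  if (!nrow(edges)) return(list())
  out_of <- split(seq_len(nrow(edges)), edges$reactant)
  acc <- vector("list", 0L)
  walk <- function(edge_seq, node_seq) {
    last <- node_seq[length(node_seq)]
    acc[[length(acc) + 1L]] <<- list(
      edge_idx = edge_seq,
      nodes = node_seq,
      is_cycle = last == node_seq[1L] && length(node_seq) > 1L
    )
    if (last == node_seq[1L] && length(node_seq) > 1L) return() # cycle closed
    if (length(edge_seq) >= max_edges) return()
    nxt <- out_of[[last]]
    if (is.null(nxt)) return()
    for (ei in nxt) { # already in edge_id order
      prod <- edges$product[ei]
      if (prod %in% node_seq[-1L]) next      # would repeat an interior node
      if (prod == node_seq[1L] || !(prod %in% node_seq))
        walk(c(edge_seq, ei), c(node_seq, prod))
    }
  }
  starts <- order(edges$edge_id) # edges are stored sorted; keep explicit
  for (ei in starts) walk(ei, c(edges$reactant[ei], edges$product[ei]))
  acc
}

#' Evaluate the signed score of one path
#'
#' Scores a path by the backward recurrence the pathway statistic is built
#' on. Each step combines the current node's expression with the signed,
#' zero-clamped continuation: when the running sign of the path is positive
#' the continuation is floored at zero, when negative it is capped at zero,
#' so a detrimental suffix can always be dropped (at the price of also
#' dropping the node where the path would have stopped). The final node of
#' the path is never clamped; it plays the leaf role of the recursion.
#'
#' @param node_values Numeric vector of node expression values along the
#'   path chain (length = edges + 1).
#' @param multipliers Integer vector in {+1, -1}, one per edge.
#' @param clamp If `FALSE`, evaluates the plain nested sum without zero
#'   clamping (useful to show what the clamp buys on adversarial examples).
#' @return List with `vmax` and `vmin`, the extremal signed scores
#'   attainable by the path under optimal suffix truncation. Without
#'   clamping the two coincide with the plain nested sum.
#' @export
path_value <- function(node_values, multipliers, clamp = TRUE) {
  L <- length(multipliers)
  stopifnot(length(node_values) == L + 1L, L >= 1L)
  vmax <- vmin <- node_values[L + 1L]
  for (k in L:1) {
    Tm <- multipliers[k]
    x <- node_values[k]
    if (clamp && k < L) {
      if (Tm > 0) {
        new_max <- x + max(0, vmax)
        new_min <- x + min(0, vmin)
      } else {
        new_max <- x - min(0, vmin)
        new_min <- x - max(0, vmax)
      }
    } else {
      if (Tm > 0) {
        new_max <- x + vmax
        new_min <- x + vmin
      } else {
        new_max <- x - vmin
        new_min <- x - vmax
      }
    }
    vmax <- new_max
    vmin <- new_min
  }
  list(vmax = vmax, vmin = vmin)
}
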