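# Core scoring engine.
#
# Every edge receives a clamped (max, min) score pair by the recursion:
# children are the edges leaving the edge's product node; an edge with no
# usable children is a leaf and scores reactant + T * product; otherwise the
# candidates are reactant + T * max_rec and reactant + T * min_rec, where
# max_rec / min_rec are the extremes of the children's *returned* (clamped)
# scores. Returns are clamped as max(max_score, 0) and min(min_score, 0), so
# a detrimental continuation can always be zeroed out. Memoization makes the
# computation linear in edges on acyclic graphs; edges already on the
# recursion stack are never re-entered, which turns cyclic graphs into a
# reproducible heuristic (entry order fixed by sorted edge_id).
#
# The engine is value-vectorized: node values may be an n_nodes x m matrix
# (e.g. one column per rotation sample) and all score arithmetic is
# elementwise, so a full rotation null costs one traversal. Backtracking
# pointers are recorded only in the scalar (m == 1) case.

deap_engine <- function(graph, node_vals, pointers = FALSE) {
  edges <- graph$edges
  ne <- nrow(edges)
  if (is.null(dim(node_vals)))
    node_vals <- matrix(node_vals, ncol = 1L,
                        dimnames = list(names(node_vals), NULL))
  m <- ncol(node_vals)
  if (pointers && m != 1L)
    stop("path pointers are only available for single-column node values")
  node_ids <- names(graph$nodes)
  ridx <- match(edges$reactant, node_ids)
  pidx <- match(edges$product, node_ids)
  children <- graph$children
  maxS <- matrix(NA_real_, ne, m)
  minS <- matrix(NA_real_, ne, m)
  done <- logical(ne)
  onstack <- logical(ne)
  ptr_max <- if (pointers) vector("list", ne) else NULL
  ptr_min <- if (pointers) vector("list", ne) else NULL

  visit <- function(ei) {
    if (done[ei] || onstack[ei]) return(invisible(NULL))
    onstack[ei] <<- TRUE
    kids_all <- children[[ei]]
    for (k in kids_all) if (!done[k] && !onstack[k]) visit(k)
    kids <- kids_all[done[kids_all]] # blocked (on-stack) children are skipped
    ER <- node_vals[ridx[ei], ]
    Tm <- edges$multiplier[ei]
    if (!length(kids)) {
      cand <- ER + Tm * node_vals[pidx[ei], ]
      mx <- cand
      mn <- cand
      if (pointers) {
        ptr_max[[ei]] <<- list(type = "leaf")
        ptr_min[[ei]] <<- list(type = "leaf")
      }
    } else {
      kmax <- maxS[kids, , drop = FALSE] # clamped, >= 0
      kmin <- minS[kids, , drop = FALSE] # clamped, <= 0
      if (m == 1L) {
        bmax <- which.max(kmax) # ties: lowest edge index = edge_id order
        bmin <- which.min(kmin)
        rec_max <- kmax[bmax]
        rec_min <- kmin[bmin]
      } else {
        rec_max <- apply(kmax, 2L, max)
        rec_min <- apply(kmin, 2L, min)
      }
      if (Tm > 0) {
        mx <- ER + rec_max
        mn <- ER + rec_min
      } else {
        mx <- ER - rec_min
        mn <- ER - rec_max
      }
      if (pointers) {
        ptr_max[[ei]] <<- if (Tm > 0) {
          if (rec_max <= 0) list(type = "trunc")
          else list(type = "child", child = kids[bmax], branch = "max")
        } else {
          if (rec_min >= 0) list(type = "trunc")
          else list(type = "child", child = kids[bmin], branch = "min")
        }
        ptr_min[[ei]] <<- if (Tm > 0) {
          if (rec_min >= 0) list(type = "trunc")
          else list(type = "child", child = kids[bmin], branch = "min")
        } else {
          if (rec_max <= 0) list(type = "trunc")
          else list(type = "child", child = kids[bmax], branch = "max")
        }
      }
    }
    maxS[ei, ] <<- pmax(mx, 0)
    minS[ei, ] <<- pmin(mn, 0)
    onstack[ei] <<- FALSE
    done[ei] <<- TRUE
    invisible(NULL)
  }

  # Seed at leaf edges (no upstream edge into the reactant node), then sweep
  # remaining unvisited edges until the edge set is exhausted (cycles).
  for (ei in leaf_edges(graph)) visit(ei)
  while (any(!done)) visit(which(!done)[1L])

  list(max_score = maxS, min_score = minS,
       ptr_max = ptr_max, ptr_min = ptr_min)
}

# Follow backtracking pointers from (edge, branch) to a node chain.
# Truncation ends the path at the current reactant node; a leaf pointer
# appends the product node. On cyclic graphs the chain is cut at the first
# repeated node unless it closes the path at its starting node.
reconstruct_path <- function(graph, eng, ei, branch) {
  edges <- graph$edges
  nodes_chain <- character(0)
  edge_chain <- integer(0)
  repeat {
    r <- edges$reactant[ei]
    if (r %in% nodes_chain) {
      if (r == nodes_chain[1L]) nodes_chain <- c(nodes_chain, r)
      break
    }
    nodes_chain <- c(nodes_chain, r)
    p <- if (branch == "max") eng$ptr_max[[ei]] else eng$ptr_min[[ei]]
    if (p$type == "leaf") {
      edge_chain <- c(edge_chain, ei)
      pr <- edges$product[ei]
      if (pr %in% nodes_chain && pr != nodes_chain[1L]) break
      nodes_chain <- c(nodes_chain, pr)
      break
    }
    if (p$type == "trunc") break
    edge_chain <- c(edge_chain, ei)
    ei <- p$child
    branch <- p$branch
  }
  list(nodes = nodes_chain, edge_idx = edge_chain)
}

#' Maximal signed-path score of a pathway
#'
#' Computes the pathway statistic: the maximum, over all edges and both
#' score branches, of the absolute clamped path score, together with the
#' path achieving it. The recursion is seeded at leaf edges and memoized;
#' see the package vignette for the exact score semantics (in particular,
#' clamping lets a path drop a detrimental suffix, and a path ends with its
#' final node counted only where the recursion bottoms out).
#'
#' @param graph A [pathway_graph].
#' @param summary Named numeric vector of per-protein values from
#'   [expression_summary()] (proteins absent from a node contribute 0).
#' @return Object of class `deap_score`: a list with `statistic` (the
#'   nonnegative score s*), `signed_score`, `path` (node-id chain),
#'   `path_edges` (edge ids), `edge_table` (per-edge clamped max/min
#'   scores), `coverage` (fraction of pathway proteins measured), and
#'   `degenerate` (TRUE when the pathway has no edges).
#' @examples
#' g <- pathway_graph("toy",
#'   nodes = list(A = "A", B = "B", C = "C"),
#'   edges = data.frame(edge_id = c("e1", "e2"),
#'                      reactant = c("A", "B"), product = c("B", "C"),
#'                      kind = "catalysis"))
#' deap_score(g, c(A = 2, B = -5, C = 1))
#' @export
deap_score <- function(graph, summary) {
  stopifnot(inherits(graph, "pathway_graph"))
  edges <- graph$edges
  if (!nrow(edges)) {
    return(structure(list(statistic = 0, signed_score = 0,
                          path = character(0), path_edges = character(0),
                          edge_table = data.frame(),
                          coverage = pathway_coverage(graph, summary),
                          degenerate = TRUE),
                     class = "deap_score"))
  }
  nv <- node_value_matrix(graph, matrix(summary, ncol = 1L,
                                        dimnames = list(names(summary), NULL)))
  eng <- deap_engine(graph, nv, pointers = TRUE)
  best_val <- -Inf
  best_edge <- NA_integer_
  best_branch <- "max"
  for (ei in seq_len(nrow(edges))) { # edge_id order; first winner kept
    if (eng$max_score[ei, 1L] > best_val) {
      best_val <- eng$max_score[ei, 1L]
      best_edge <- ei
      best_branch <- "max"
    }
    if (-eng$min_score[ei, 1L] > best_val) {
      best_val <- -eng$min_score[ei, 1L]
      best_edge <- ei
      best_branch <- "min"
    }
  }
  if (best_val <= 0) {
    path <- list(nodes = character(0), edge_idx = integer(0))
    signed <- 0
    best_val <- 0
  } else {
    path <- reconstruct_path(graph, eng, best_edge, best_branch)
    signed <- if (best_branch == "max") eng$max_score[best_edge, 1L]
              else eng$min_score[best_edge, 1L]
  }
  structure(list(
    statistic = best_val,
    signed_score = signed,
    path = path$nodes,
    path_edges = edges$edge_id[path$edge_idx],
    edge_table = data.frame(edge_id = edges$edge_id,
                            max_score = eng$max_score[, 1L],
                            min_score = eng$min_score[, 1L],
                            stringsAsFactors = FALSE),
    coverage = pathway_coverage(graph, summary),
    degenerate = FALSE
  ), class = "deap_score")
}

#' @export
print.deap_score <- function(x, ...) {
  cat(sprintf("<deap_score> s* = %.4g (signed %.4g)\n", x$statistic, x$signed_score))
  if (length(x$path)) cat("  path:", format_path(x), "\n")
  invisible(x)
}

# "A -> B -| C" rendering of the best path (-| marks an inhibitory step).
format_path <- function(score, graph = NULL, edge_kinds = NULL) {
  nodes <- score$path
  if (!length(nodes)) return("")
  kinds <- edge_kinds
  if (is.null(kinds) && !is.null(graph))
    kinds <- graph$edges$kind[match(score$path_edges, graph$edges$edge_id)]
  out <- nodes[1L]
  for (k in seq_along(nodes)[-1L]) {
    sep <- if (!is.null(kinds) && k - 1L <= length(kinds) &&
               identical(kinds[k - 1L], "inhibition")) "-|" else "->"
    out <- paste(out, sep, nodes[k])
  }
  out
}

#' Matrix form of the pathway statistic
#'
#' Evaluates the statistic for many per-protein summary columns at once
#' (one column per rotation or replicate) in a single graph traversal.
#' Column j of the result equals `deap_score(graph, E_mat[, j])$statistic`.
#'
#' @param graph A [pathway_graph].
#' @param E_mat Numeric matrix, proteins x m, with protein rownames.
#' @return Numeric vector of m nonnegative statistics.
#' @export
deap_score_matrix <- function(graph, E_mat) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!nrow(graph$edges)) return(rep(0, ncol(E_mat)))
  nv <- node_value_matrix(graph, E_mat)
  eng <- deap_engine(graph, nv, pointers = FALSE)
  stat <- rep(0, ncol(nv))
  for (ei in seq_len(nrow(graph$edges))) {
    stat <- pmax(stat, eng$max_score[ei, ], -eng$min_score[ei, ])
  }
  stat
}

#' Brute-force path-enumeration score (test oracle)
#'
#' Independent evaluation of the pathway statistic by exhaustive path
#' enumeration: every sink-terminated simple path and every simple cycle is
#' scored with the backward clamped recurrence of [path_value()], and the
#' maximum absolute score is returned. Sink-terminated chains suffice
#' because the clamp lets any path drop its suffix from an interior edge
#' onward, so every attainable score arises from some complete chain. On
#' acyclic graphs this agrees exactly with [deap_score()]; on cyclic graphs
#' the memoized recursion is an order-dependent heuristic and may diverge.
#'
#' @param graph A [pathway_graph].
#' @param summary Named numeric per-protein summary vector.
#' @param max_edges Enumeration bound on path length (default: all edges).
#' @param max_paths Guard on the number of enumerated paths.
#' @return List with `statistic`, `signed_score`, `path` (node chain), and
#'   `path_edges`.
#' @export
brute_force_score <- function(graph, summary, max_edges = nrow(graph$edges),
                              max_paths = 2e5) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!nrow(graph$edges))
    return(list(statistic = 0, signed_score = 0, path = character(0),
                path_edges = character(0)))
  paths <- enumerate_paths(graph, max_edges)
  if (length(paths) > max_paths)
    stop("path enumeration exceeds max_paths = ", max_paths,
         "; graph too large for the brute-force oracle")
  nv <- node_value_matrix(graph, matrix(summary, ncol = 1L,
                                        dimnames = list(names(summary), NULL)))
  sinks <- setdiff(names(graph$nodes), unique(graph$edges$reactant))
  best <- list(statistic = 0, signed_score = 0, path = character(0),
               path_edges = character(0))
  for (p in paths) {
    terminal <- p$is_cycle || p$nodes[length(p$nodes)] %in% sinks
    if (!terminal) next
    vals <- nv[p$nodes, 1L]
    pv <- path_value(vals, graph$edges$multiplier[p$edge_idx])
    stat <- max(pv$vmax, -pv$vmin, 0)
    if (stat > best$statistic) { # strict: lexicographically first path wins ties
      best <- list(
        statistic = stat,
        signed_score = if (pv$vmax >= -pv$vmin) pv$vmax else pv$vmin,
        path = p$nodes,
        path_edges = graph$edges$edge_id[p$edge_idx]
      )
    }
  }
  best
}
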