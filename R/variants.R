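# Alternative pathway statistics. All share the matrix interface
# (graph, E_mat) -> numeric vector so they plug into the same rotation
# machinery as the main score; "user" statistics with that interface can be
# benchmarked alongside.

unsign_graph <- function(graph) {
  g <- graph
  g$edges$kind <- "catalysis"
  g$edges$multiplier <- 1L
  g
}

#' Build a pathway statistic function
#'
#' Returns a closure `E_mat -> numeric` evaluating the chosen statistic for
#' each column of a protein-by-m summary matrix on a fixed pathway graph.
#'
#' Available kinds:
#' * `"deap"` - the maximal signed-path score.
#' * `"length_normalized"` - the score divided by the number of nodes in
#'   its best path.
#' * `"unsigned"` - the score with every edge multiplier forced to +1.
#' * `"whole_pathway_sum"` - absolute sum over all edges of
#'   `E(reactant) + T * E(product)`; the whole-graph analogue that does not
#'   search for a best path.
#' * `"set_based"` - absolute mean of E over the pathway's member proteins,
#'   ignoring topology.
#'
#' @param kind Statistic name (see above).
#' @param graph A [pathway_graph].
#' @return Function mapping a protein x m matrix (protein rownames) to a
#'   length-m nonnegative numeric vector.
#' @export
statistic_function <- function(kind, graph) {
  kind <- match.arg(kind, c("deap", "length_normalized", "unsigned",
                            "whole_pathway_sum", "set_based"))
  switch(kind,
    deap = function(E_mat) deap_score_matrix(graph, E_mat),
    unsigned = {
      ug <- unsign_graph(graph)
      function(E_mat) deap_score_matrix(ug, E_mat)
    },
    length_normalized = function(E_mat) {
      vapply(seq_len(ncol(E_mat)), function(j) {
        sc <- deap_score(graph, stats::setNames(E_mat[, j], rownames(E_mat)))
        if (!length(sc$path)) 0 else sc$statistic / length(unique(sc$path))
      }, 0)
    },
    whole_pathway_sum = function(E_mat) {
      nv <- node_value_matrix(graph, E_mat)
      ridx <- match(graph$edges$reactant, names(graph$nodes))
      pidx <- match(graph$edges$product, names(graph$nodes))
      Tm <- graph$edges$multiplier
      contrib <- nv[ridx, , drop = FALSE] + Tm * nv[pidx, , drop = FALSE]
      abs(colSums(contrib))
    },
    set_based = {
      members <- pathway_proteins(graph)
      function(E_mat) {
        idx <- match(members, rownames(E_mat))
        idx <- idx[!is.na(idx)]
        if (!length(idx)) return(rep(0, ncol(E_mat)))
        abs(colMeans(E_mat[idx, , drop = FALSE]))
      }
    })
}

#' Evaluate one pathway statistic variant
#'
#' Convenience scalar wrapper around [statistic_function()].
#'
#' @param kind Statistic name (see [statistic_function()]); `"deap"` gives
#'   the main score.
#' @param graph A [pathway_graph].
#' @param summary Named per-protein summary vector.
#' @return Single nonnegative statistic value.
#' @export
variant_statistic <- function(kind, graph, summary) {
  fn <- statistic_function(kind, graph)
  E <- matrix(summary, ncol = 1L, dimnames = list(names(summary), NULL))
  fn(E)[1L]
}
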