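test_that("edge scores on a three-node chain match hand evaluation", {
  g <- chain_graph(c("A", "B", "C"))
  sc <- deap_score(g, c(A = 2, B = -5, C = 1))
  tab <- sc$edge_table
  expect_equal(tab$max_score[tab$edge_id == "e02"], 0)   # B->C clamped above
  expect_equal(tab$min_score[tab$edge_id == "e02"], -4)
  expect_equal(tab$max_score[tab$edge_id == "e01"], 2)
  expect_equal(tab$min_score[tab$edge_id == "e01"], -2)
  expect_equal(sc$statistic, 4)
  expect_equal(sc$signed_score, -4)
  expect_equal(sc$path, c("B", "C"))
})

test_that("terminal edges score reactant plus signed product", {
  g <- chain_graph(c("X", "Y"), "inhibition")
  sc <- deap_score(g, c(X = 1, Y = -1))
  expect_equal(sc$edge_table$max_score, 2) # 1 - (-1)
  expect_equal(sc$edge_table$min_score, 0)
  expect_equal(sc$statistic, 2)
  g0 <- chain_graph(c("X", "Y"))
  expect_equal(deap_score(g0, c(X = 0, Y = 0))$edge_table$max_score, 0)
  expect_equal(deap_score(g0, c(X = 0, Y = 0))$edge_table$min_score, 0)
})

test_that("a coherent inhibitory string scores its full alternating path", {
  ids <- paste0("N", 1:5)
  g <- chain_graph(ids, "inhibition")
  E <- stats::setNames(c(1, -1, 1, -1, 1), ids)
  sc <- deap_score(g, E)
  expect_equal(sc$statistic, 5) # every node contributes +1 after sign flips
  expect_equal(sc$signed_score, 5)
  expect_equal(sc$path, ids)
})

test_that("the branching pathway isolates its coherent sub-path", {
  g <- branching_graph8()
  E <- stats::setNames(rep(0, 8), paste0("A", 1:8))
  E[c("A3", "A4", "A7")] <- 1
  bf <- brute_force_score(g, E)
  expect_equal(bf$statistic, 3)
  expect_equal(bf$path, c("A3", "A4", "A7"))
  sc <- deap_score(g, E)
  expect_equal(sc$statistic, 3)
  expect_equal(sc$path, c("A3", "A4", "A7"))
})

test_that("degenerate inputs give zero statistics and flagged results", {
  g <- chain_graph(c("A", "B", "C"))
  sc <- deap_score(g, c(A = 0, B = 0, C = 0))
  expect_equal(sc$statistic, 0)
  expect_length(sc$path, 0)
  lonely <- pathway_graph("lonely", list(A = "A"),
                          data.frame(edge_id = character(0),
                                     reactant = character(0),
                                     product = character(0),
                                     kind = character(0)))
  sc0 <- deap_score(lonely, c(A = 3))
  expect_true(sc0$degenerate)
  expect_equal(sc0$statistic, 0)
})

test_that("single-edge closed form: |a + b| under catalysis", {
  set.seed(7)
  for (i in 1:20) {
    ab <- rnorm(2)
    g <- chain_graph(c("A", "B"))
    expect_equal(brute_force_score(g, c(A = ab[1], B = ab[2]))$statistic,
                 abs(sum(ab)))
    expect_equal(deap_score(g, c(A = ab[1], B = ab[2]))$statistic, abs(sum(ab)))
  }
})

test_that("recursion and brute-force oracle agree exactly on random DAGs", {
  set.seed(321)
  for (i in 1:300) {
    g <- random_dag(sample(3:10, 1))
    E <- random_summary(g)
    expect_equal(deap_score(g, E)$statistic, brute_force_score(g, E)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("negating the data flips the signed score but not the statistic", {
  set.seed(99)
  for (i in 1:50) {
    g <- random_dag(sample(3:8, 1))
    E <- random_summary(g)
    a <- deap_score(g, E)
    b <- deap_score(g, -E)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$signed_score, -b$signed_score)
  }
})

test_that("extending a positive chain with a positive node increases the score", {
  set.seed(55)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    ids <- sprintf("P%d", seq_len(k + 1))
    E <- stats::setNames(abs(rnorm(k + 1)), ids)
    s_before <- deap_score(chain_graph(ids[1:k]), E[1:k])$statistic
    s_after <- deap_score(chain_graph(ids), E)$statistic
    expect_gt(s_after, s_before)
  }
})

test_that("zero clamping never hurts, and strictly helps on detrimental suffixes", {
  # clamped vs plain evaluation over the same sink-terminated paths
  clamp_free_stat <- function(g, E) {
    nv <- deapr:::node_value_matrix(g, matrix(E, ncol = 1,
                                              dimnames = list(names(E), NULL)))
    sinks <- setdiff(names(g$nodes), unique(g$edges$reactant))
    best <- 0
    for (p in enumerate_paths(g, nrow(g$edges))) {
      if (!(p$is_cycle || p$nodes[length(p$nodes)] %in% sinks)) next
      pv <- path_value(nv[p$nodes, 1], g$edges$multiplier[p$edge_idx],
                       clamp = FALSE)
      best <- max(best, abs(pv$vmax))
    }
    best
  }
  set.seed(77)
  for (i in 1:40) {
    g <- random_dag(sample(3:8, 1))
    E <- random_summary(g)
    expect_gte(deap_score(g, E)$statistic, clamp_free_stat(g, E) - 1e-12)
  }
  g <- chain_graph(c("A", "B", "C"))
  E <- c(A = 5, B = -0.5, C = 0.2) # dropping the suffix beats keeping it
  expect_equal(deap_score(g, E)$statistic, 5)
  expect_equal(clamp_free_stat(g, E), 4.7)
})

test_that("identical inputs give identical results across runs", {
  g <- branching_graph8()
  E <- stats::setNames(sin(1:8), paste0("A", 1:8))
  expect_identical(deap_score(g, E), deap_score(g, E))
})

test_that("the matrix engine matches the scalar score column by column", {
  set.seed(42)
  for (i in 1:10) {
    g <- random_dag(sample(3:9, 1))
    m <- 20
    E_mat <- matrix(rnorm(length(g$nodes) * m), ncol = m,
                    dimnames = list(names(g$nodes), NULL))
    vec <- deap_score_matrix(g, E_mat)
    ref <- vapply(seq_len(m), function(j)
      deap_score(g, stats::setNames(E_mat[, j], rownames(E_mat)))$statistic, 0)
    expect_equal(vec, ref)
  }
})

test_that("cyclic graphs score reproducibly and cover every edge", {
  g <- pathway_graph("cyc", list(A = "A", B = "B", C = "C"),
                     data.frame(edge_id = c("e1", "e2", "e3"),
                                reactant = c("A", "B", "C"),
                                product = c("B", "C", "A"),
                                kind = "catalysis"))
  E <- c(A = 1, B = 2, C = 3)
  sc1 <- deap_score(g, E)
  expect_identical(sc1, deap_score(g, E))
  expect_false(any(is.na(sc1$edge_table$max_score)))
  # entry fixed at e1; e1 is blocked on re-entry so e3 bottoms out as a leaf
  # counting A again: the best chain is the closed cycle 1 + (2 + (3 + 1))
  expect_equal(sc1$statistic, 7)
  expect_equal(sc1$path, c("A", "B", "C", "A"))
  # self-loop as an explicit single-edge cycle
  gs <- pathway_graph("self", list(A = "A"),
                      data.frame(edge_id = "e1", reactant = "A",
                                 product = "A", kind = "catalysis"))
  expect_equal(deap_score(gs, c(A = 2))$statistic, 4)
})

test_that("variant statistics match their definitions", {
  ids <- paste0("N", 1:5)
  g <- chain_graph(ids, "inhibition")
  E <- stats::setNames(c(1, -1, 1, -1, 1), ids)
  expect_equal(variant_statistic("length_normalized", g, E), 1) # 5 / 5 nodes
  gc <- chain_graph(ids, "catalysis")
  Ec <- stats::setNames(rnorm(5), ids)
  expect_equal(variant_statistic("unsigned", gc, Ec),
               variant_statistic("deap", gc, Ec))
  g2 <- chain_graph(c("A", "B"))
  expect_equal(variant_statistic("set_based", g2, c(A = 1, B = -1)), 0)
  # whole-pathway sum: sum over edges of E(reactant) + T * E(product)
  g3 <- chain_graph(c("A", "B", "C"), c("catalysis", "inhibition"))
  E3 <- c(A = 1, B = 2, C = 3)
  expect_equal(variant_statistic("whole_pathway_sum", g3, E3),
               abs((1 + 2) + (2 - 3)))
  expect_error(statistic_function("nonsense", g3), "arg")
})
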