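test_that("pathway table parsing builds graphs with set-valued node identity", {
  f <- as_tsv_file(pathway_tsv_text(c(
    "P1\te1\tA3\tA4\tactivation",
    "P1\te2\tA1\tA4\tinhibition",
    "P1\te3\tA4\tA7\tactivation",
    "P1\te4\tA2\tA5\tactivation",
    "P1\te5\tA5\tA7\tactivation",
    "P1\te6\tA3\tA6\tactivation",
    "P1\te7\tA6\tA8\tactivation",
    "P1\te8\tA6\tA7\tactivation",
    "P2\tf1\tX;Y\tZ\tactivation",
    "P2\tf2\tY;X\tW\tactivation")))
  graphs <- parse_pathway_table(f)
  expect_named(graphs, c("P1", "P2"))
  expect_length(graphs$P1$nodes, 8)
  expect_equal(nrow(graphs$P1$edges), 8)
  expect_equal(sum(graphs$P1$edges$kind == "inhibition"), 1)
  expect_equal(graphs$P1$edges$multiplier[graphs$P1$edges$edge_id == "e2"], -1L)
  # member sets listed in different order collapse to one shared node
  expect_length(graphs$P2$nodes, 3)
  expect_setequal(graphs$P2$nodes[["X;Y"]], c("X", "Y"))
})

test_that("a single edge row yields a two-node one-edge pathway", {
  graphs <- parse_pathway_table(as_tsv_file(
    pathway_tsv_text("P1\te1\tA\tB\tactivation")))
  expect_length(graphs, 1)
  expect_length(graphs$P1$nodes, 2)
  expect_equal(nrow(graphs$P1$edges), 1)
})

test_that("malformed pathway tables are rejected with informative errors", {
  expect_error(parse_pathway_table(as_tsv_file(
    pathway_tsv_text("P1\te1\tA\tB\tbinds"))), "binds")
  expect_error(parse_pathway_table(as_tsv_file(
    pathway_tsv_text("P1\te1\t;\tB\tactivation"))), "empty")
  f <- as_tsv_file("pathway_id\tedge_id\treactants\tinteraction\nP\te\tA\tactivation")
  expect_error(parse_pathway_table(f), "missing column")
})

test_that("parallel edges collapse only when their kind matches", {
  g <- pathway_graph("p", list(A = "A", B = "B"),
                     data.frame(edge_id = c("e1", "e2", "e3"),
                                reactant = "A", product = "B",
                                kind = c("catalysis", "catalysis", "inhibition")))
  expect_equal(nrow(g$edges), 2)
  expect_setequal(g$edges$kind, c("catalysis", "inhibition"))
})

test_that("writing and re-parsing a pathway table is a field-level round trip", {
  g1 <- branching_graph8()
  g2 <- chain_graph(c("X", "Y", "Z"), c("catalysis", "inhibition"), "chain3")
  f <- tempfile(fileext = ".tsv")
  write_pathway_table(list(branching8 = g1, chain3 = g2), f)
  back <- parse_pathway_table(f)
  for (orig in list(g1, g2)) {
    got <- back[[orig$pathway_id]]
    expect_equal(got$nodes[order(names(got$nodes))],
                 orig$nodes[order(names(orig$nodes))])
    expect_equal(got$edges, orig$edges)
  }
})

test_that("the adjacency index matches a from-scratch rebuild", {
  set.seed(101)
  for (i in 1:10) {
    g <- random_dag(sample(3:9, 1))
    expect_identical(g$children, build_adjacency(g))
  }
  # and it is what the edge table says it is
  g <- branching_graph8()
  for (ei in seq_len(nrow(g$edges))) {
    kids <- which(g$edges$reactant == g$edges$product[ei])
    expect_identical(g$children[[ei]], sort(kids))
  }
})

test_that("path enumeration covers chains, cycles, and nothing twice", {
  g <- branching_graph8()
  paths <- enumerate_paths(g, max_edges = 3)
  chains <- vapply(paths, function(p) paste(p$nodes, collapse = ""), "")
  for (expected in c("A3A4A7", "A1A4A7", "A2A5A7", "A3A6A8", "A3A6A7"))
    expect_true(expected %in% chains, label = expected)
  expect_false(anyDuplicated(vapply(paths, function(p)
    paste(p$edge_idx, collapse = ","), "")) > 0)
  # no interior node repeats; cycles close only at the first node
  for (p in paths) {
    interior <- p$nodes[-length(p$nodes)]
    expect_false(anyDuplicated(interior) > 0)
    if (p$is_cycle) expect_identical(p$nodes[1], p$nodes[length(p$nodes)])
  }
  # single edge graph: exactly one path
  expect_length(enumerate_paths(chain_graph(c("A", "B")), 5), 1)
})

test_that("a three-node cycle enumerates its rotations and sub-chains", {
  g <- pathway_graph("cyc", list(A = "A", B = "B", C = "C"),
                     data.frame(edge_id = c("e1", "e2", "e3"),
                                reactant = c("A", "B", "C"),
                                product = c("B", "C", "A"),
                                kind = "catalysis"))
  paths <- enumerate_paths(g, 3)
  # hand enumeration: 3 single edges, 3 two-edge chains, 3 cycle rotations
  expect_length(paths, 9)
  expect_equal(sum(vapply(paths, `[[`, TRUE, "is_cycle")), 3)
})

test_that("enumeration counts agree with an independent DFS oracle on DAGs", {
  set.seed(202)
  for (i in 1:25) {
    g <- random_dag(sample(3:9, 1))
    cap <- sample(2:6, 1)
    expect_length(enumerate_paths(g, cap), dfs_count_paths(g, cap))
  }
})

test_that("minimal SBML import maps reactions and inhibitory modifiers", {
  sbml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m1">',
    '<listOfSpecies>',
    '<species id="s1" name="P00001"/><species id="s2" name="P00002"/>',
    '<species id="s3" name="P00003"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="r1">',
    '<listOfReactants><speciesReference species="s1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="s2"/></listOfProducts>',
    '<listOfModifiers><modifierSpeciesReference species="s3" sboTerm="SBO:0000020"/></listOfModifiers>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  graphs <- import_sbml_minimal(f)
  g <- graphs$m1
  expect_length(g$nodes, 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$kind[g$edges$reactant == "P00003"], "inhibition")
  # equivalent edge-list text yields the same graph up to ids
  ref <- parse_pathway_table(as_tsv_file(pathway_tsv_text(c(
    "m1\tr1\tP00001\tP00002\tactivation",
    "m1\tr1_mod1\tP00003\tP00002\tinhibition"))))$m1
  expect_equal(g$nodes[order(names(g$nodes))], ref$nodes[order(names(ref$nodes))])
  expect_equal(g$edges[c("reactant", "product", "kind")],
               ref$edges[c("reactant", "product", "kind")])
})

test_that("degenerate SBML inputs warn or error rather than failing silently", {
  f <- tempfile(fileext = ".xml")
  writeLines(paste0('<sbml xmlns="http://www.sbml.org/sbml/level2/version4">',
                    '<model id="empty"/></sbml>'), f)
  expect_warning(graphs <- import_sbml_minimal(f), "no usable reactions")
  expect_length(graphs, 0)
  writeLines("this is not xml <<<", f)
  expect_error(import_sbml_minimal(f))
})

test_that("GMT gene sets are read for the set-based variant", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tP1\tP2\tP3", "setB\tdesc\tP2\tP4"), f)
  sets <- read_gmt(f)
  expect_named(sets, c("setA", "setB"))
  expect_setequal(sets$setA, c("P1", "P2", "P3"))
  writeLines("broken\tonly_two_fields", f)
  expect_error(read_gmt(f), "fewer than 3")
})
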