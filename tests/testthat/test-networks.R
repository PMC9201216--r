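write_edges <- function(lines, path = withr::local_tempfile(
                          fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

test_that("interactome loading deduplicates, thresholds and round-trips", {
  p <- write_edges(c("protein1 protein2 combined_score",
                     "A B 900", "B A 900", "B C 399", "C D 400",
                     "D D 950", "A C 150", "A C 700"))
  g <- load_interactome(p, confidence_threshold = 400)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(g), 3L)           # A-B, C-D, A-C
  expect_false(igraph::are_adjacent(g, "B", "C"))  # 399 < 400 dropped
  expect_equal(igraph::E(g)$score[igraph::get_edge_ids(g, c("A", "C"))], 700L)
  expect_equal(sum(igraph::which_loop(g)), 0L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(g, out)
  g2 <- load_interactome(out, confidence_threshold = 0)
  expect_true(igraph::is_isomorphic_to(g, g2))
  ids <- igraph::get_edge_ids(g2, t(igraph::as_edgelist(g)))
  expect_equal(igraph::E(g2)$score[ids], igraph::E(g)$score)
})

test_that("interactome parser reports bad lines and applies alias maps", {
  bad <- write_edges(c("A B 900", "B C"))
  expect_error(load_interactome(bad), "line 2")
  nonnum <- write_edges(c("A B 900", "B C high"))
  expect_error(load_interactome(nonnum), "line 2")
  p <- write_edges(c("9606.ENSP1 9606.ENSP2 700"))
  al <- data.frame(external_id = c("9606.ENSP1", "9606.ENSP2"),
                   symbol = c("TP53", "MDM2"))
  g <- load_interactome(p, confidence_threshold = 400, aliases = al)
  expect_setequal(igraph::V(g)$name, c("TP53", "MDM2"))
})

test_that("patient networks contain direct and single-intermediary seed paths", {
  # seeds connected directly to each other
  g <- path_graph(2, c("A", "B"))
  nw <- build_sample_network(c("A", "B"), g, sample_id = "s")
  expect_setequal(network_nodes(nw), c("A", "B"))
  expect_equal(igraph::ecount(nw$graph), 1L)
  expect_equal(sort(igraph::V(nw$graph)$role), c("seed", "seed"))

  # seeds connected via a single intermediary protein: B is imputed
  g <- path_graph(3, c("A", "B", "C"))
  nw <- build_sample_network(c("A", "C"), g)
  expect_setequal(network_nodes(nw), c("A", "B", "C"))
  role <- igraph::V(nw$graph)$role
  names(role) <- igraph::V(nw$graph)$name
  expect_equal(unname(role["B"]), "imputed")

  # a seed pair at distance 3 contributes nothing; the largest-component
  # tie-break keeps the lexicographically smallest singleton
  g <- path_graph(4, c("A", "B", "C", "D"))
  nw <- build_sample_network(c("A", "D"), g)
  expect_equal(network_nodes(nw), "A")

  # seeds absent from the interactome are dropped and recorded
  nw <- build_sample_network(c("A", "B", "ZZ"), path_graph(2, c("A", "B")))
  expect_equal(nw$seeds_dropped, "ZZ")
  expect_error(build_sample_network(c("X", "Y"), path_graph(2, c("A", "B"))),
               "empty-network")
  expect_error(build_sample_network(character(0), path_graph(2)), "empty seed")
})

test_that("network construction equals brute-force length-<=2 path enumeration", {
  set.seed(77)
  for (i in 1:25) {
    g <- random_test_graph(sample(10:50, 1), p = runif(1, 0.05, 0.3))
    seeds <- sample(igraph::V(g)$name, sample(2:8, 1))
    or <- oracle_network(seeds, g)
    nw <- build_sample_network(seeds, g, largest_component = FALSE)
    got <- graph_sets(nw$graph)
    expect_identical(got$nodes, or$nodes)
    expect_identical(got$edges, or$edges)
    # every imputed node has degree >= 2 pre-restriction
    role <- igraph::V(nw$graph)$role
    expect_true(all(igraph::degree(nw$graph)[role == "imputed"] >= 2))
  }
})

test_that("adding a seed never removes a pre-restriction node", {
  set.seed(12)
  for (i in 1:10) {
    g <- random_test_graph(30, p = 0.12)
    seeds <- sample(igraph::V(g)$name, 4)
    extra <- sample(setdiff(igraph::V(g)$name, seeds), 1)
    n1 <- network_nodes(build_sample_network(seeds, g,
                                             largest_component = FALSE))
    n2 <- network_nodes(build_sample_network(c(seeds, extra), g,
                                             largest_component = FALSE))
    expect_true(all(n1 %in% n2))
  }
})

test_that("imputed-imputed edges are excluded unless requested", {
  # square A-X-B-Y-A plus edge X-Y: X and Y both impute for seeds {A,B}
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "X", "B", "Y", "X"),
               to   = c("X", "B", "Y", "A", "Y")), directed = FALSE)
  nw <- build_sample_network(c("A", "B"), g)
  expect_setequal(network_nodes(nw), c("A", "B", "X", "Y"))
  expect_equal(igraph::ecount(nw$graph), 4L)   # X-Y excluded
  nw2 <- build_sample_network(c("A", "B"), g, keep_imputed_edges = TRUE)
  expect_equal(igraph::ecount(nw2$graph), 5L)
})

test_that("networks serialize to GraphML with role attributes", {
  g <- path_graph(3, c("A", "B", "C"))
  nw <- build_sample_network(c("A", "C"), g)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(nw, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
  expect_setequal(igraph::V(g2)$role, c("seed", "imputed", "seed"))
})
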