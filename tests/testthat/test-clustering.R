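test_that("Jaccard distance follows its definition on node sets", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a", "b"), c("c", "d")), 1)
  expect_equal(jaccard_distance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(d <- jaccard_distance(character(0), character(0)))
  expect_equal(d, 1)
})

test_that("Jaccard distance is a metric on node sets", {
  set.seed(5)
  pool <- letters
  sets <- replicate(12, sample(pool, sample(3:10, 1)), simplify = FALSE)
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- suppressWarnings(jaccard_distance(sets[[i]], sets[[j]]))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("edge-set Jaccard is available behind a flag", {
  g1 <- path_graph(3, c("a", "b", "c"))
  g2 <- path_graph(3, c("b", "c", "d"))
  # shared edge b-c; union {a-b, b-c, c-d}
  expect_equal(jaccard_distance(g1, g2, on = "edges"), 1 - 1 / 3)
})

test_that("UPGMA reproduces the two-sample case and the hclust oracle", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("s1", "s2"),
                                                    c("s1", "s2")))
  dend <- upgma(d)
  expect_equal(dend$hclust$height, 0.4)
  expect_equal(newick(dend), "(s1:0.4,s2:0.4);")

  set.seed(30)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    dend <- upgma(m)
    oracle <- stats::cophenetic(stats::hclust(stats::as.dist(m),
                                              method = "average"))
    expect_equal(as.matrix(cophenetic_distances(dend))[sprintf("s%02d", 1:n),
                                                       sprintf("s%02d", 1:n)],
                 as.matrix(oracle)[sprintf("s%02d", 1:n), sprintf("s%02d", 1:n)],
                 tolerance = 1e-12)
    expect_true(all(diff(dend$hclust$height) >= -1e-12))  # ultrametric
  }
})

test_that("UPGMA tie-breaking is lexicographic by smallest member id", {
  n <- 4
  m <- matrix(0.7, n, n); diag(m) <- 0
  dimnames(m) <- list(c("d", "b", "c", "a"), c("d", "b", "c", "a"))
  dend <- upgma(m)
  expect_equal(dend$hclust$height, rep(0.7, 3))
  # first merge joins the two lexicographically smallest labels
  expect_setequal(dend$members[[1]], c("a", "b"))
})

test_that("UPGMA rejects malformed distance input", {
  m <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgma(m), "NA")
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")
  asym <- matrix(c(0, 0.2, 0.4, 0), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgma(asym), "symmetric")
})

test_that("newick output round-trips through ape with correct branch lengths", {
  skip_if_not_installed("ape")
  set.seed(9)
  n <- 6
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.2, 0.9)
  m <- m + t(m)
  labs <- sprintf("t%d", 1:n)
  dimnames(m) <- list(labs, labs)
  dend <- upgma(m)
  tr <- ape::read.tree(text = newick(dend))
  expect_setequal(tr$tip.label, labs)
  # leaf-to-leaf path length in the tree = 2 x merge height
  coph <- as.matrix(cophenetic_distances(dend))
  tree_d <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(tree_d, 2 * coph[labs, labs], tolerance = 1e-8)
})

test_that("2x2 Fisher matches enumeration, handles forced tables, is symmetric", {
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  expect_equal(fisher_exact_2x2(8, 2, 1, 9), oracle_fisher_2x2(8, 2, 1, 9),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(8, 2, 1, 9),
               stats::fisher.test(rbind(c(8, 2), c(1, 9)))$p.value,
               tolerance = 1e-7)
  set.seed(64)
  for (i in 1:30) {
    x <- sample(0:12, 4, replace = TRUE)
    p <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    expect_equal(p, oracle_fisher_2x2(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12)
    # invariant under simultaneous row and column swap
    expect_equal(p, fisher_exact_2x2(x[4], x[3], x[2], x[1]),
                 tolerance = 1e-12)
  }
})

test_that("cluster testing finds enriched nodes and respects min_size", {
  # 8 samples: 4 cases tightly clustered, 4 controls tightly clustered
  ids <- c(sprintf("ca%d", 1:4), sprintf("ko%d", 1:4))
  phen <- data.frame(sample_id = ids,
                     status = rep(c("case", "control"), each = 4))
  m <- matrix(0.9, 8, 8, dimnames = list(ids, ids))
  m[1:4, 1:4] <- 0.1; m[5:8, 5:8] <- 0.1; diag(m) <- 0
  dend <- upgma(m)
  cl <- significant_clusters(dend, phen, min_size = 3, alpha = 0.05)
  sig <- cl[cl$significant, ]
  expect_true(any(sig$dominance == "case" & sig$n_cases == 4 &
                    sig$n_controls == 0))
  expect_true(any(sig$dominance == "control" & sig$n_controls == 4 &
                    sig$n_cases == 0))
  # maximal significant nodes: the two pure blocks, not the root
  expect_true(all(cl$size[cl$maximal] <= 4))
  # p-value equals the 2x2 oracle on the node composition
  r <- sig[sig$dominance == "case", ][1, ]
  expect_equal(r$p_value,
               oracle_fisher_2x2(r$n_cases, r$n_controls,
                                 4 - r$n_cases, 4 - r$n_controls),
               tolerance = 1e-12)
  expect_equal(nrow(significant_clusters(dend, phen, min_size = 99)), 0L)
})

test_that("cluster composition p-value matches a study-sized hypergeometric oracle", {
  # synthetic composition: a 68-member node with 47 cases out of 61/82
  expect_equal(fisher_exact_2x2(47, 21, 14, 61),
               oracle_fisher_2x2(47, 21, 14, 61), tolerance = 1e-12)
  # a node whose composition equals the cohort ratio is never more extreme
  p_prop <- fisher_exact_2x2(30, 40, 31, 42)
  expect_gt(p_prop, fisher_exact_2x2(47, 21, 14, 61))
})

test_that("layered networks union members with support counts and roles", {
  g <- path_graph(4, c("A", "B", "C", "D"))
  n1 <- build_sample_network(c("A", "C"), g, sample_id = "s1")
  n2 <- build_sample_network(c("A", "C"), g, sample_id = "s2")
  n3 <- build_sample_network(c("B", "D"), g, sample_id = "s3")
  nets <- list(s1 = n1, s2 = n2, s3 = n3)
  # single member: layered equals the member with unit supports
  lay1 <- build_layered_network("s1", nets)
  expect_setequal(network_nodes(lay1), network_nodes(n1))
  expect_true(all(igraph::V(lay1$graph)$support == 1L))
  # two identical networks: all supports 2
  lay2 <- build_layered_network(c("s1", "s2"), nets)
  expect_true(all(igraph::V(lay2$graph)$support == 2L))
  expect_true(all(igraph::E(lay2$graph)$support == 2L))
  # roles: B is imputed in s1/s2 but a seed in s3 -> seed-in-any
  lay3 <- build_layered_network(c("s1", "s2", "s3"), nets)
  role <- igraph::V(lay3$graph)$role
  names(role) <- igraph::V(lay3$graph)$name
  expect_equal(unname(role["B"]), "seed")
  expect_error(build_layered_network(c("s1", "s9"), nets), "missing member")
})

test_that("layered support counts equal an independent recount", {
  set.seed(21)
  g <- random_test_graph(40, p = 0.15)
  nets <- list()
  for (i in 1:5) {
    seeds <- sample(igraph::V(g)$name, 6)
    nets[[sprintf("m%d", i)]] <- build_sample_network(
      seeds, g, sample_id = sprintf("m%d", i))
  }
  lay <- build_layered_network(names(nets), nets)
  sup <- igraph::V(lay$graph)$support
  names(sup) <- igraph::V(lay$graph)$name
  for (v in names(sup)) {
    recount <- sum(vapply(nets, function(nw) v %in% network_nodes(nw), TRUE))
    expect_equal(unname(sup[v]), recount)
  }
  expect_gte(igraph::vcount(lay$graph),
             max(vapply(nets, function(nw) igraph::vcount(nw$graph),
                        numeric(1))))
})

test_that("unique genes are node-set differences annotated with roles", {
  g <- path_graph(5, c("A", "B", "C", "D", "E"))
  n1 <- build_sample_network(c("A", "C"), g, sample_id = "s1")
  n2 <- build_sample_network(c("C", "E"), g, sample_id = "s2")
  nets <- list(s1 = n1, s2 = n2)
  la <- build_layered_network("s1", nets)
  lb <- build_layered_network("s2", nets)
  ug <- unique_genes(la, lb)
  expect_equal(ug$a_only$gene, c("A", "B"))
  expect_equal(ug$b_only$gene, c("D", "E"))
  expect_equal(ug$a_only$role[ug$a_only$gene == "B"], "imputed")
  same <- unique_genes(la, la)
  expect_equal(nrow(same$a_only), 0L)
  expect_equal(nrow(same$b_only), 0L)
})
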