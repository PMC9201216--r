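test_that("preferential-attachment backbone has the hand-derived edge counts", {
  # m = 1: complete core K2 (1 edge) + one edge per later node -> tree
  cfg <- sim_config(n_interactome_nodes = 5, attachment_degree = 1,
                    n_communities = 0, module_size = 2, rng_seed = 11)
  g <- generate_interactome(cfg)
  expect_equal(igraph::ecount(g), 4)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::vcount(g) - 1, igraph::ecount(g))  # tree

  # hand-stepped n = 6, m = 2: core K3 has 3 edges, nodes 4..6 add 2 each
  cfg <- sim_config(n_interactome_nodes = 6, attachment_degree = 2,
                    n_communities = 0, module_size = 2, rng_seed = 11)
  expect_equal(igraph::ecount(generate_interactome(cfg)), 3 + 2 * 3)

  # general count for the growth rule
  cfg <- sim_config(n_interactome_nodes = 200, attachment_degree = 3,
                    n_communities = 0, module_size = 5, rng_seed = 2)
  expect_equal(igraph::ecount(generate_interactome(cfg)),
               choose(4, 2) + 3 * (200 - 4))
})

test_that("interactome generation is deterministic and scores are in range", {
  cfg <- small_config(seed = 5)
  g1 <- generate_interactome(cfg)
  g2 <- generate_interactome(cfg)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_identical(igraph::E(g1)$score, igraph::E(g2)$score)
  expect_true(all(igraph::E(g1)$score >= 150 & igraph::E(g1)$score <= 999))
  expect_true(igraph::is_connected(g1))
  expect_false(igraph::any_multiple(g1))
  expect_equal(sum(igraph::which_loop(g1)), 0L)
})

test_that("community overlay wires dense local neighborhoods", {
  cfg <- sim_config(n_interactome_nodes = 100, attachment_degree = 2,
                    n_communities = 3, community_size = 10,
                    community_density = 1, module_size = 5, rng_seed = 3)
  g <- generate_interactome(cfg)
  # with density 1 every community is a clique: the graph holds 3 disjoint
  # 10-cliques, so at least 3 * choose(10,2) edges beyond a spanning core
  expect_gte(igraph::ecount(g), 3 * choose(10, 2))
  cl <- igraph::max_cliques(g, min = 10)
  expect_gte(length(cl), 3)
})

test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(case_module_hit_rate = 1.2), "case_module_hit_rate")
  expect_error(sim_config(module_size = 1000, n_interactome_nodes = 1000),
               "module_size")
  expect_error(sim_config(n_cases = 1, n_controls = 2), "at least 4")
  expect_error(sim_config(n_interactome_nodes = 3, attachment_degree = 3,
                          n_communities = 0, module_size = 2),
               "attachment_degree")
})

test_that("planted module is a connected induced subgraph of requested size", {
  # trivial sizes
  g <- path_graph(4, c("a", "b", "c", "d"))
  expect_length(plant_disease_module(g, 1, rng_seed = 1), 1)
  expect_setequal(plant_disease_module(g, 4, rng_seed = 1),
                  c("a", "b", "c", "d"))
  # module_size = 2 on a path graph must be an adjacent pair (all connected
  # 2-sets of a path are its edges)
  for (s in 1:10) {
    mod <- plant_disease_module(g, 2, rng_seed = s)
    expect_true(igraph::are_adjacent(g, mod[1], mod[2]))
  }
  # general property on the default generator
  for (s in 1:5) {
    cfg <- small_config(seed = s)
    gg <- generate_interactome(cfg)
    mod <- plant_disease_module(gg, cfg$module_size, rng_seed = s)
    expect_length(mod, cfg$module_size)
    expect_true(igraph::is_connected(igraph::induced_subgraph(gg, mod)))
  }
})

test_that("module planting fails cleanly on disconnected graphs", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c"), to = c("b", "d")), directed = FALSE)
  expect_error(plant_disease_module(g, 3, rng_seed = 1), "simulation error")
})

test_that("degenerate hit rates produce exactly the promised carriers", {
  cfg <- small_config(seed = 7, case_module_hit_rate = 1,
                      control_module_hit_rate = 0,
                      quality_fail_rate = 0, missing_genotype_rate = 0)
  g <- generate_interactome(cfg)
  mod <- plant_disease_module(g, cfg$module_size, rng_seed = 7)
  sim <- generate_cohort(cfg, g, mod, withr::local_tempdir())
  v <- sim$variants
  mod_rows <- v$sites$gene %in% mod
  carried <- colSums(v$geno[mod_rows, , drop = FALSE] >= 1, na.rm = TRUE)
  st <- sim$phenotypes$status[match(names(carried),
                                    sim$phenotypes$sample_id)]
  expect_true(all(carried[st == "case"] >= 1))
  expect_true(all(carried[st == "control"] == 0))
})

test_that("an all-zero design yields an empty variant set", {
  cfg <- small_config(seed = 2, case_module_hit_rate = 0,
                      control_module_hit_rate = 0,
                      background_variants_per_sample = 0,
                      n_density_clusters = 0)
  g <- generate_interactome(cfg)
  mod <- plant_disease_module(g, cfg$module_size, rng_seed = 2)
  sim <- generate_cohort(cfg, g, mod, withr::local_tempdir())
  expect_equal(length(sim$variants), 0L)
})

test_that("identical configurations give byte-identical output files", {
  cfg <- small_config(seed = 9)
  g <- generate_interactome(cfg)
  mod <- plant_disease_module(g, cfg$module_size, rng_seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_cohort(cfg, g, mod, d1)
  s2 <- generate_cohort(cfg, g, mod, d2)
  for (f in c("vcf", "annotations", "phenotypes", "truth")) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                     info = f)
  }
})

test_that("written files round-trip through the readers", {
  cfg <- small_config(seed = 4)
  g <- generate_interactome(cfg)
  mod <- plant_disease_module(g, cfg$module_size, rng_seed = 4)
  sim <- generate_cohort(cfg, g, mod, withr::local_tempdir())
  v <- read_cohort(sim$paths$vcf, sim$paths$annotations)
  expect_equal(length(v), length(sim$variants))
  expect_identical(colnames(v$geno), colnames(sim$variants$geno))
  expect_identical(unname(v$geno), unname(sim$variants$geno))
  expect_equal(v$sites$polyphen2_hdiv, sim$variants$sites$polyphen2_hdiv,
               tolerance = 1e-9)
  ph <- read_phenotypes(sim$paths$phenotypes)
  expect_identical(ph, sim$phenotypes)
  # annotation row count cross-checked by an independent parse of both files
  ann <- read.table(sim$paths$annotations, header = TRUE, sep = "\t")
  vcf_body <- grep("^[^#]", readLines(sim$paths$vcf), value = TRUE)
  expect_equal(nrow(ann), length(vcf_body))
  expect_equal(nrow(ann), nrow(sim$truth$site_flags))
})

test_that("planted truth flags reproduce the deleteriousness filter outcome", {
  cfg <- small_config(seed = 6)
  g <- generate_interactome(cfg)
  mod <- plant_disease_module(g, cfg$module_size, rng_seed = 6)
  sim <- generate_cohort(cfg, g, mod, withr::local_tempdir())
  res <- deleteriousness_filter(sim$variants)
  expect_setequal(res$variants$sites$pos,
                  sim$truth$site_flags$pos[sim$truth$site_flags$passing_deleterious])
  # and every sample's hit list stays inside the module
  expect_true(all(unlist(sim$truth$hits) %in% mod))
})
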