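# Independent oracles, deliberately implemented with different formulas /
# algorithms than the package code they check.

# Two-sided exact p for a 2x3 table by full enumeration with the
# factorial form  P(T) = (prod r_i!)(prod c_j!) / (n! prod t_ij!).
oracle_fisher_2x3 <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (r[1L] == 0 || r[2L] == 0) return(1)
  const <- sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(n)
  probs <- numeric(0); pobs <- NA_real_
  for (a in 0:cs[1L]) for (b in 0:cs[2L]) {
    cc <- r[1L] - a - b
    if (cc < 0 || cc > cs[3L]) next
    lp <- const - (lfactorial(a) + lfactorial(b) + lfactorial(cc) +
                     lfactorial(cs[1L] - a) + lfactorial(cs[2L] - b) +
                     lfactorial(cs[3L] - cc))
    probs <- c(probs, exp(lp))
    if (a == tab[1L, 1L] && b == tab[1L, 2L]) pobs <- exp(lp)
  }
  min(1, sum(probs[probs <= pobs * (1 + 1e-12)]))
}

# Two-sided exact p for a 2x2 table, factorial-form enumeration.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
    lfactorial(n - c1) - lfactorial(n) -
    (lfactorial(ks) + lfactorial(r1 - ks) + lfactorial(c1 - ks) +
       lfactorial(n - r1 - c1 + ks))
  pr <- exp(lp)
  pobs <- pr[ks == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

# Brute-force patient-network construction: enumerate all simple paths of
# length <= 2 between all seed pairs; nodes are path nodes plus isolated
# mapped seeds, edges are path edges (canonical "a|b" keys).
oracle_network <- function(seeds, g) {
  nm <- igraph::V(g)$name
  seeds <- intersect(unique(seeds), nm)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  dimnames(A) <- list(nm, nm)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|")
  nodes <- seeds
  edges <- character(0)
  if (length(seeds) >= 2L) {
    for (i in seq_len(length(seeds) - 1L)) {
      for (j in seq.int(i + 1L, length(seeds))) {
        a <- seeds[i]; b <- seeds[j]
        if (A[a, b])
          edges <- c(edges, key(a, b))
        for (w in setdiff(nm, c(a, b))) {
          if (A[a, w] && A[w, b])
            edges <- c(edges, key(a, w), key(w, b))
        }
      }
    }
  }
  enodes <- unique(unlist(strsplit(edges, "|", fixed = TRUE)))
  list(nodes = sort(unique(c(nodes, enodes))), edges = sort(unique(edges)))
}

# Node and canonical edge keys of a sample network graph.
graph_sets <- function(graph) {
  e <- igraph::as_edgelist(graph)
  list(nodes = sort(igraph::V(graph)$name),
       edges = sort(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]),
                          sep = "|")))
}

# Hand-rolled BFS hop distances from one node over an adjacency list.
oracle_bfs <- function(adj, start) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (!is.finite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# Separation score recomputed from scratch with hand BFS.
oracle_separation <- function(set_a, set_b, g) {
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  ia <- match(intersect(set_a, nm), nm)
  ib <- match(intersect(set_b, nm), nm)
  src <- unique(c(ia, ib))
  dmat <- t(vapply(src, function(s) oracle_bfs(adj, s), numeric(length(nm))))
  drow <- function(u) dmat[match(u, src), ]
  nearest <- function(u, set, exclude_self = FALSE) {
    tt <- if (exclude_self) setdiff(set, u) else set
    if (!length(tt)) return(Inf)
    min(drow(u)[tt])
  }
  within <- function(set) {
    v <- vapply(set, nearest, 1, set = set, exclude_self = TRUE)
    mean(v[is.finite(v)])
  }
  cross <- c(vapply(ia, nearest, 1, set = ib),
             vapply(ib, nearest, 1, set = ia))
  mean(cross[is.finite(cross)]) - (within(ia) + within(ib)) / 2
}

# Exact over-representation p by complete enumeration of all draws of
# size |query| from a small universe.
oracle_ora <- function(query, reference, universe) {
  k_obs <- length(intersect(query, reference))
  draws <- utils::combn(universe, length(query))
  hits <- apply(draws, 2L, function(d) length(intersect(d, reference)))
  mean(hits >= k_obs)
}

# Random 2xC genotype-style table with margins bounded by max_margin.
random_table <- function(ncol = 3L, max_margin = 12L) {
  repeat {
    tab <- matrix(sample(0:4, 2L * ncol, replace = TRUE), nrow = 2L)
    if (all(rowSums(tab) > 0) && all(rowSums(tab) <= max_margin) &&
        all(colSums(tab) <= max_margin))
      return(tab)
  }
}

# Small Erdos-Renyi-ish random graph with named nodes.
random_test_graph <- function(n, p = 0.15, scores = TRUE) {
  nm <- sprintf("N%02d", seq_len(n))
  prs <- utils::combn(nm, 2L)
  keep <- stats::runif(ncol(prs)) < p
  g <- igraph::graph_from_data_frame(
    data.frame(from = prs[1L, keep], to = prs[2L, keep]),
    directed = FALSE, vertices = data.frame(name = nm))
  if (scores) igraph::E(g)$score <- sample(400:999, igraph::ecount(g),
                                           replace = TRUE)
  g
}

# Path graph with named nodes n1 - n2 - ... - nk.
path_graph <- function(k, names = paste0("n", seq_len(k))) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = names[-k], to = names[-1L]),
    directed = FALSE, vertices = data.frame(name = names))
  igraph::E(g)$score <- 900L
  g
}

# Minimal annotated variant set from a site spec data.frame; genotype
# matrix defaults to a single sample carrying everything heterozygous.
make_variants <- function(sites, geno = NULL) {
  if (nrow(sites) == 0L) {
    v <- make_variants(data.frame(pos = 1L))
    return(subset_variants_0(v))
  }
  defaults <- data.frame(chrom = "1", pos = seq_len(nrow(sites)) * 1000L,
                         ref = "A", alt = "G", qual = 60, depth = 30,
                         qd = 10, fs = 10, xamb = 0, gene = "GENE1",
                         func = "exonic", polyphen2_hdiv = 0.99, sift = 0.01,
                         cadd_phred = 25, maf_ref = 0.01,
                         rsid = sprintf("rs%03d", seq_len(nrow(sites))),
                         stringsAsFactors = FALSE)
  for (nmx in names(sites)) defaults[[nmx]] <- sites[[nmx]]
  if (is.null(geno))
    geno <- matrix(1L, nrow = nrow(sites), ncol = 1L,
                   dimnames = list(NULL, "s1"))
  ppin_variants(defaults, geno)
}

# Zero-row subset of a ppin_variants (keeps column structure).
subset_variants_0 <- function(v) {
  ppin_variants(v$sites[integer(0), , drop = FALSE],
                v$geno[integer(0), , drop = FALSE])
}

# Tiny simulation config for fast end-to-end tests; `...` overrides.
small_config <- function(seed = 1L, ...) {
  args <- list(n_cases = 12L, n_controls = 14L, n_interactome_nodes = 200L,
               attachment_degree = 3L, n_communities = 6L,
               community_size = 12L, module_size = 8L,
               background_variants_per_sample = 40L,
               fraction_deleterious_background = 0.1,
               rng_seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Rewrite a multi-sample VCF with its sample columns permuted.
permute_vcf_samples <- function(path, out, perm_seed = 1L) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  ns <- length(fields) - 9L
  set.seed(perm_seed)
  perm <- sample.int(ns)
  reorder <- function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    paste(c(f[1:9], f[9L + perm]), collapse = "\t")
  }
  body <- seq.int(hdr, length(lines))
  lines[body] <- vapply(lines[body], reorder, "", USE.NAMES = FALSE)
  writeLines(lines, out)
  out
}
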