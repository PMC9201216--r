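#' Simulation configuration for a synthetic case/control exome cohort
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' cohort design, interactome size and topology, the planted disease module,
#' per-group module hit rates, background variant load, and nuisance rates
#' (quality-field failures, missing genotypes). The defaults emulate a
#' 61-case / 82-control early-onset preeclampsia exome design with a 15-gene
#' disease module preferentially hit by deleterious variants in cases.
#'
#' @param n_cases,n_controls Number of case and control samples.
#' @param n_interactome_nodes Number of genes (nodes) in the synthetic
#'   interactome.
#' @param attachment_degree Edges added per new node during
#'   preferential-attachment growth of the interactome backbone.
#' @param n_communities,community_size,community_density Dense local
#'   communities overlaid on the backbone, emulating protein complexes and
#'   pathway modules: `n_communities` disjoint random node sets of
#'   `community_size` members are wired internally with edge probability
#'   `community_density`. Scale-free growth alone yields vanishing local
#'   clustering; the overlay gives the locally dense neighborhoods from
#'   which disease modules are carved. Set `n_communities = 0` for a pure
#'   preferential-attachment graph.
#' @param module_size Number of genes in the planted disease module
#'   (a connected induced subgraph of the interactome).
#' @param case_module_hit_rate,control_module_hit_rate Probability that a
#'   case (resp. control) sample carries at least one planted deleterious
#'   variant in a module gene.
#' @param background_variants_per_sample Number of background variants drawn
#'   per sample in random non-module genes.
#' @param fraction_deleterious_background Proportion of background variant
#'   sites whose annotations pass the deleteriousness filter; the remainder
#'   violate exactly one threshold.
#' @param quality_fail_rate Probability that a site draws values failing
#'   site-quality filtering, split evenly across the five quality fields
#'   (multimapping, depth, quality, QD, strand bias); each field fails with
#'   rate `1 - (1 - quality_fail_rate)^(1/5)`.
#' @param n_density_clusters Number of 3-variant clusters planted within a
#'   10-bp window so the variant-density filter has work to do.
#' @param missing_genotype_rate Probability that a non-carrier genotype is
#'   recorded as missing (`./.`).
#' @param rng_seed Integer seed; identical configurations give byte-identical
#'   output files.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cases = 61L, n_controls = 82L,
                       n_interactome_nodes = 1000L,
                       attachment_degree = 3L,
                       n_communities = 30L,
                       community_size = 20L,
                       community_density = 0.9,
                       module_size = 15L,
                       case_module_hit_rate = 0.8,
                       control_module_hit_rate = 0.05,
                       background_variants_per_sample = 150L,
                       fraction_deleterious_background = 0.05,
                       quality_fail_rate = 0.05,
                       n_density_clusters = 5L,
                       missing_genotype_rate = 0.01,
                       rng_seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_interactome_nodes = as.integer(n_interactome_nodes),
              attachment_degree = as.integer(attachment_degree),
              n_communities = as.integer(n_communities),
              community_size = as.integer(community_size),
              community_density = community_density,
              module_size = as.integer(module_size),
              case_module_hit_rate = case_module_hit_rate,
              control_module_hit_rate = control_module_hit_rate,
              background_variants_per_sample =
                as.integer(background_variants_per_sample),
              fraction_deleterious_background = fraction_deleterious_background,
              quality_fail_rate = quality_fail_rate,
              n_density_clusters = as.integer(n_density_clusters),
              missing_genotype_rate = missing_genotype_rate,
              rng_seed = as.integer(rng_seed))
  for (f in c("n_cases", "n_controls", "n_interactome_nodes",
              "attachment_degree", "module_size")) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("configuration error: '", f, "' must be a positive count",
           call. = FALSE)
  }
  for (f in c("background_variants_per_sample", "n_density_clusters",
              "n_communities")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("configuration error: '", f, "' must be a non-negative count",
           call. = FALSE)
  }
  for (f in c("case_module_hit_rate", "control_module_hit_rate",
              "fraction_deleterious_background", "quality_fail_rate",
              "missing_genotype_rate", "community_density")) {
    p <- cfg[[f]]
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop("configuration error: '", f, "' must be a probability in [0,1]",
           call. = FALSE)
  }
  if (cfg$module_size >= cfg$n_interactome_nodes)
    stop("configuration error: 'module_size' must be smaller than ",
         "'n_interactome_nodes'", call. = FALSE)
  if (cfg$n_cases + cfg$n_controls < 4L)
    stop("configuration error: 'n_cases' + 'n_controls' must be at least 4",
         call. = FALSE)
  if (cfg$n_interactome_nodes < cfg$attachment_degree + 1L)
    stop("configuration error: 'n_interactome_nodes' must be at least ",
         "'attachment_degree' + 1", call. = FALSE)
  if (cfg$n_communities > 0L) {
    if (cfg$community_size < 2L)
      stop("configuration error: 'community_size' must be at least 2",
           call. = FALSE)
    if (cfg$n_communities * cfg$community_size > cfg$n_interactome_nodes)
      stop("configuration error: communities ('n_communities' x ",
           "'community_size') cannot exceed 'n_interactome_nodes'",
           call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic interactome: scale-free backbone + dense communities
#'
#' Grows an undirected simple graph in two layers. The backbone is grown by
#' preferential attachment — a complete core of `attachment_degree + 1`
#' nodes, then one node at a time, each attaching `attachment_degree` edges
#' to distinct existing nodes sampled with probability proportional to
#' current degree — giving the hub-dominated degree distribution of curated
#' interaction databases. On top of the backbone, `n_communities` disjoint
#' random node sets of `community_size` members are wired internally with
#' edge probability `community_density`, emulating the locally dense
#' protein complexes and pathway modules that pure scale-free growth cannot
#' produce (its local clustering vanishes with size). Duplicate edges are
#' merged. Each edge carries an integer confidence score drawn uniformly
#' from 150-999, so load-time confidence thresholds behave as with
#' STRING-style input.
#'
#' With `n_communities = 0` the backbone edge count is exactly
#' `choose(m + 1, 2) + m * (n - m - 1)` for `n` nodes and attachment degree
#' `m`; with `m = 1` the graph is a tree.
#'
#' @param config A [sim_config()].
#' @return An [igraph::igraph] with vertex names `"G0001"`, ... and an
#'   integer edge attribute `score`.
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_interactome_nodes
  m <- config$attachment_degree
  set.seed(config$rng_seed)
  width <- max(4L, nchar(as.character(n)))
  nm <- sprintf(paste0("G%0", width, "d"), seq_len(n))
  core <- utils::combn(seq_len(m + 1L), 2L)
  n_bb <- ncol(core) + m * (n - m - 1L)
  from <- integer(n_bb); to <- integer(n_bb)
  from[seq_len(ncol(core))] <- core[1L, ]
  to[seq_len(ncol(core))] <- core[2L, ]
  deg <- integer(n)
  deg[seq_len(m + 1L)] <- m
  k <- ncol(core)
  if (n > m + 1L) {
    for (v in seq.int(m + 2L, n)) {
      targets <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)])
      idx <- k + seq_len(m)
      from[idx] <- targets
      to[idx] <- v
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
      k <- k + m
    }
  }
  cfrom <- integer(0); cto <- integer(0)
  if (config$n_communities > 0L) {
    pool <- sample.int(n, config$n_communities * config$community_size)
    for (ci in seq_len(config$n_communities)) {
      mem <- pool[(ci - 1L) * config$community_size +
                    seq_len(config$community_size)]
      prs <- utils::combn(sort(mem), 2L)
      keep <- runif(ncol(prs)) < config$community_density
      cfrom <- c(cfrom, prs[1L, keep])
      cto <- c(cto, prs[2L, keep])
    }
  }
  edges <- data.frame(from = nm[c(from, cfrom)], to = nm[c(to, cto)],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nm))
  g <- igraph::simplify(g)
  igraph::E(g)$score <- sample(150:999, igraph::ecount(g), replace = TRUE)
  igraph::graph_attr(g, "confidence_threshold") <- 0L
  g
}

#' Plant a connected disease module in an interactome
#'
#' Selects `module_size` genes forming a connected induced subgraph by
#' random-walk expansion from a degree-weighted random start node (the
#' stationary distribution of a walk on the graph): at each step a
#' frontier node (a non-member adjacent to the current members) is added,
#' sampled with probability proportional to the fourth power of its edge count
#' into the current member set. This strongly cohesion-biased weighting keeps the walk
#' inside locally dense neighborhoods, so the planted module is both
#' connected and cohesive — the topology expected of a disease module.
#'
#' @param interactome An igraph, e.g. from [generate_interactome()].
#' @param module_size Number of genes to select; at most the node count.
#' @param rng_seed Integer seed.
#' @return Character vector of module gene symbols (sorted).
#' @export
plant_disease_module <- function(interactome, module_size, rng_seed = 1L) {
  n <- igraph::vcount(interactome)
  module_size <- as.integer(module_size)
  if (module_size < 1L || module_size > n)
    stop("configuration error: 'module_size' must be in [1, node count]",
         call. = FALSE)
  set.seed(as.integer(rng_seed))
  nm <- igraph::V(interactome)$name
  adj <- igraph::as_adj_list(interactome)
  deg <- igraph::degree(interactome)
  members <- sample.int(n, 1L, prob = pmax(deg, 1L))
  while (length(members) < module_size) {
    frontier <- setdiff(unique(unlist(lapply(adj[members], as.integer))),
                        members)
    if (length(frontier) == 0L)
      stop("simulation error: random walk cannot reach ", module_size,
           " connected nodes (graph component too small)", call. = FALSE)
    w <- vapply(adj[frontier],
                function(nb) sum(as.integer(nb) %in% members), 1L)
    members <- c(members,
                 frontier[sample.int(length(frontier), 1L, prob = w^2)])
  }
  sort(nm[members])
}

# Draw annotation scores for one batch of sites. Passing sites satisfy all
# four deleteriousness thresholds; failing sites violate exactly one,
# drawn away from the boundary so filter outcomes are unambiguous.
draw_annotations <- function(n_sites, passing) {
  ann <- data.frame(func = rep("exonic", n_sites),
                    polyphen2_hdiv = runif(n_sites, 0.957, 1),
                    sift = runif(n_sites, 0, 0.049),
                    cadd_phred = runif(n_sites, 15.1, 40),
                    maf_ref = runif(n_sites, 0, 0.049),
                    stringsAsFactors = FALSE)
  fail <- which(!passing)
  if (length(fail)) {
    which_thr <- sample.int(4L, length(fail), replace = TRUE)
    pp <- fail[which_thr == 1L]
    ann$polyphen2_hdiv[pp] <- runif(length(pp), 0, 0.95)
    sf <- fail[which_thr == 2L]
    ann$sift[sf] <- runif(length(sf), 0.06, 1)
    cd <- fail[which_thr == 3L]
    ann$cadd_phred[cd] <- runif(length(cd), 0, 14.9)
    mf <- fail[which_thr == 4L]
    ann$maf_ref[mf] <- runif(length(mf), 0.06, 0.5)
  }
  ann
}

# Draw site-level quality fields; `rate` is the overall per-site failure
# probability, split evenly across the five fields; values are kept clear
# of the filter thresholds so outcomes are unambiguous.
draw_quality <- function(n_sites, rate) {
  per_field <- 1 - (1 - rate)^(1 / 5)
  fail <- matrix(runif(n_sites * 5L) < per_field, nrow = n_sites)
  data.frame(
    qual = ifelse(fail[, 1L], round(runif(n_sites, 2, 29), 1),
                  round(runif(n_sites, 35, 90), 1)),
    depth = ifelse(fail[, 2L], sample(1:9, n_sites, replace = TRUE),
                   sample(12:80, n_sites, replace = TRUE)),
    qd = ifelse(fail[, 3L], round(runif(n_sites, 0.05, 1.4), 2),
                round(runif(n_sites, 2, 30), 2)),
    fs = ifelse(fail[, 4L], round(runif(n_sites, 201, 400), 1),
                round(runif(n_sites, 0, 150), 1)),
    xamb = ifelse(fail[, 5L], sample(4:8, n_sites, replace = TRUE),
                  sample(0:3, n_sites, replace = TRUE)))
}

#' Simulate a case/control exome cohort with a planted disease module
#'
#' Generates per-sample variants and writes a multi-sample VCF, a variant
#' annotation table, a phenotype file, and a JSON record of the planted
#' ground truth. With probability equal to its group's module hit rate, a
#' sample carries 1-3 heterozygous deleterious variants in distinct random
#' module genes (each module gene has one canonical site shared by all its
#' carriers). Every sample additionally carries
#' `background_variants_per_sample` variants in random non-module genes;
#' a configurable fraction of those sites pass the deleteriousness filter
#' and the rest violate exactly one threshold. Site quality fields are drawn
#' so that roughly `quality_fail_rate` of sites fail each quality filter,
#' and a few 3-variant clusters within 10 bp exercise the density filter.
#'
#' @param config A [sim_config()].
#' @param interactome Interactome igraph whose vertex names are the gene
#'   universe.
#' @param module Character vector of module genes (subset of the
#'   interactome's nodes), e.g. from [plant_disease_module()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with file `paths` (vcf, annotations,
#'   phenotypes, truth), the `truth` list (module genes, per-sample hit
#'   lists, per-site `passing_deleterious` and `quality_ok` flags), and the
#'   in-memory `variants` ([ppin_variants]) and `phenotypes` data frame.
#' @export
generate_cohort <- function(config, interactome, module, dir) {
  stopifnot(inherits(config, "sim_config"))
  genes <- igraph::V(interactome)$name
  if (!all(module %in% genes))
    stop("configuration error: 'module' must be a subset of interactome nodes",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$rng_seed)

  samples <- c(sprintf("case_%03d", seq_len(config$n_cases)),
               sprintf("ctrl_%03d", seq_len(config$n_controls)))
  status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  gene_idx <- stats::setNames(seq_along(genes), genes)
  non_module <- setdiff(genes, module)

  # --- planted module hits -------------------------------------------------
  hit_rate <- ifelse(status == "case", config$case_module_hit_rate,
                     config$control_module_hit_rate)
  is_hit <- runif(length(samples)) < hit_rate
  hit_samples <- character(0); hit_genes <- character(0)
  # 1-3 module variants per hit sample, weighted toward multiple hits
  # (affected samples typically carry more than one deleterious module allele)
  kmax <- min(3L, length(module))
  kw <- c(0.1, 0.2, 0.7)[seq_len(kmax)]
  for (i in which(is_hit)) {
    k <- sample.int(kmax, 1L, prob = kw)
    gs <- if (length(module) == 1L) module else sample(module, k)
    hit_samples <- c(hit_samples, rep(samples[i], length(gs)))
    hit_genes <- c(hit_genes, gs)
  }
  # per-sample site draw among ten per-gene positions; samples may share a
  # site or not, duplicates merge at the site level
  mod_off <- (sample.int(10L, length(hit_genes), replace = TRUE) + 4L) * 100L
  ev_mod <- data.frame(sample = hit_samples, gene = hit_genes,
                       pos = unname(gene_idx[hit_genes]) * 10000L + mod_off,
                       ref = rep("A", length(hit_genes)),
                       alt = rep("G", length(hit_genes)),
                       gt = rep(1L, length(hit_genes)),
                       stringsAsFactors = FALSE)

  # --- background variants -------------------------------------------------
  nbg <- config$background_variants_per_sample
  ev_bg <- NULL
  if (nbg > 0L) {
    bg_gene <- unlist(lapply(samples, function(s)
      sample(non_module, min(nbg, length(non_module)))))
    bg_sample <- rep(samples, each = min(nbg, length(non_module)))
    offs <- sample.int(50L, length(bg_gene), replace = TRUE) * 100L
    ev_bg <- data.frame(sample = bg_sample, gene = bg_gene,
                        pos = gene_idx[bg_gene] * 10000L + offs,
                        ref = "C", alt = "T",
                        gt = sample(c(1L, 2L), length(bg_gene),
                                    replace = TRUE, prob = c(0.9, 0.1)),
                        stringsAsFactors = FALSE)
  }

  # --- density-filter clusters (3 variants within 10 bp) -------------------
  ev_dn <- NULL
  if (config$n_density_clusters > 0L && length(non_module) > 0L) {
    dg <- sample(non_module, config$n_density_clusters,
                 replace = length(non_module) < config$n_density_clusters)
    base <- gene_idx[dg] * 10000L
    ev_dn <- data.frame(
      sample = sample(samples, 3L * config$n_density_clusters, replace = TRUE),
      gene = rep(dg, each = 3L),
      pos = as.integer(rep(base, each = 3L) + c(51L, 54L, 57L)),
      ref = "C", alt = "T", gt = 1L, stringsAsFactors = FALSE)
  }

  ev <- rbind(ev_mod, ev_bg, ev_dn)
  if (is.null(ev) || nrow(ev) == 0L) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        qual = numeric(0), depth = numeric(0),
                        qd = numeric(0), fs = numeric(0), xamb = numeric(0),
                        gene = character(0), func = character(0),
                        polyphen2_hdiv = numeric(0), sift = numeric(0),
                        cadd_phred = numeric(0), maf_ref = numeric(0),
                        rsid = character(0), stringsAsFactors = FALSE)
    geno <- matrix(integer(0), nrow = 0L, ncol = length(samples),
                   dimnames = list(NULL, sort(samples)))
  } else {
    # unique sites, ordered by position; annotations drawn once per site
    site_key <- ev$pos
    usite <- !duplicated(site_key)
    sdf <- ev[usite, c("gene", "pos", "ref", "alt")]
    sdf <- sdf[order(sdf$pos), ]
    ns <- nrow(sdf)
    in_density <- sdf$pos %% 10000L %in% c(51L, 54L, 57L)
    is_module_site <- sdf$gene %in% module
    passing <- is_module_site |
      (runif(ns) < config$fraction_deleterious_background)
    ann <- draw_annotations(ns, passing)
    qual <- draw_quality(ns, config$quality_fail_rate)
    quality_ok <- !in_density & qual$qual >= 30 & qual$depth >= 10 &
      qual$qd >= 1.5 & qual$fs <= 200 & qual$xamb < 4

    sites <- data.frame(chrom = "1", pos = sdf$pos, ref = sdf$ref,
                        alt = sdf$alt, qual = qual$qual, depth = qual$depth,
                        qd = qual$qd, fs = qual$fs, xamb = qual$xamb,
                        gene = sdf$gene, func = ann$func,
                        polyphen2_hdiv = ann$polyphen2_hdiv, sift = ann$sift,
                        cadd_phred = ann$cadd_phred, maf_ref = ann$maf_ref,
                        rsid = sprintf("sv%06d", seq_len(ns)),
                        stringsAsFactors = FALSE)

    geno <- matrix(0L, nrow = ns, ncol = length(samples),
                   dimnames = list(NULL, samples))
    row_of <- stats::setNames(seq_len(ns), as.character(sites$pos))
    geno[cbind(row_of[as.character(ev$pos)],
               match(ev$sample, samples))] <- ev$gt
    if (config$missing_genotype_rate > 0) {
      miss <- matrix(runif(length(geno)) < config$missing_genotype_rate,
                     nrow = ns)
      miss[geno != 0L] <- FALSE          # carriers stay observed
      geno[miss] <- NA_integer_
    }
    ord <- order(colnames(geno))
    geno <- geno[, ord, drop = FALSE]
  }

  phen <- data.frame(sample_id = samples, status = status,
                     stringsAsFactors = FALSE)
  phen <- phen[order(phen$sample_id), ]
  variants <- ppin_variants(sites, geno)

  truth <- list(
    module_genes = sort(module),
    hits = lapply(stats::setNames(samples, samples), function(s)
      sort(unique(ev_mod$gene[ev_mod$sample == s]))),
    site_flags = data.frame(pos = sites$pos,
                            gene = sites$gene,
                            passing_deleterious =
                              if (nrow(sites)) passing else logical(0),
                            quality_ok =
                              if (nrow(sites)) quality_ok else logical(0)))

  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                annotations = file.path(dir, "annotations.tsv"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                truth = file.path(dir, "truth.json"))
  write_cohort_vcf(variants, paths$vcf)
  write_annotations(variants, paths$annotations)
  utils::write.table(phen, paths$phenotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth, variants = variants,
                 phenotypes = phen))
}
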