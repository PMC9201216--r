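#' Control parameters for the end-to-end analysis
#'
#' Collects every tunable of the pipeline with the standard defaults:
#' the quality thresholds (depth 10, quality 30, QD 1.5, FS 200,
#' multimapping 3, 3 variants / 10 bp density rule), the deleteriousness
#' thresholds (PolyPhen-2 HDIV 0.957, SIFT 0.05, CADD 15, reference MAF
#' 0.05), the per-sample seed-gene count k = 60, interactome confidence
#' threshold 400, maximum seed-connection path length 2 (direct seed-seed
#' edges or a single imputed intermediary), cluster testing (minimum size
#' 3, alpha 0.05, no multiplicity correction), and Monte Carlo settings
#' for large genotype tables.
#'
#' @param min_depth,min_qual,min_qd,max_fs,max_xamb Quality thresholds, see
#'   [quality_filter()].
#' @param density_window,density_count Density rule, see [quality_filter()].
#' @param min_polyphen,max_sift,min_cadd,max_maf Deleteriousness
#'   thresholds, see [deleteriousness_filter()].
#' @param seed_gene_count Seed genes per sample (k).
#' @param confidence_threshold Interactome confidence cutoff.
#' @param keep_imputed_edges,largest_component Network construction
#'   options, see [build_sample_network()].
#' @param jaccard_on `"nodes"` (default) or `"edges"`.
#' @param min_cluster_size,alpha,correction Cluster testing options, see
#'   [significant_clusters()].
#' @param max_tables,mc_reps,mc_seed Genotype-test options, see
#'   [gtest_variants()].
#' @return A named list of class `ppin_control`.
#' @export
ppin_control <- function(min_depth = 10, min_qual = 30, min_qd = 1.5,
                         max_fs = 200, max_xamb = 3,
                         density_window = 10L, density_count = 3L,
                         min_polyphen = 0.957, max_sift = 0.05,
                         min_cadd = 15, max_maf = 0.05,
                         seed_gene_count = 60L,
                         confidence_threshold = 400,
                         keep_imputed_edges = FALSE,
                         largest_component = TRUE,
                         jaccard_on = "nodes",
                         min_cluster_size = 3L, alpha = 0.05,
                         correction = "none",
                         max_tables = 1e6, mc_reps = 1e5, mc_seed = 1L) {
  ctrl <- as.list(environment())
  class(ctrl) <- "ppin_control"
  ctrl
}

#' Case/control exome-to-network analysis
#'
#' Runs the full multivariate pipeline on a cohort: site-quality filtering,
#' deleteriousness filtering, per-variant 2x3 case/control Fisher genotype
#' testing, per-patient seed-gene selection (top k by genotype-test p among
#' genes the patient carries qualifying variants in), per-patient PPI
#' network construction on the interactome with paths of length at most
#' two, pairwise Jaccard distances, UPGMA clustering, per-cluster 2x2
#' Fisher case/control enrichment, layered networks and unique genes for
#' the headline case- and control-dominated clusters, and the interactome
#' separation score between those unique gene sets.
#'
#' @param vcf Path to a multi-sample VCF, or a [ppin_variants] object.
#' @param annotations Path to the annotation TSV (ignored when `vcf` is
#'   already a [ppin_variants]).
#' @param phenotypes Path to the phenotype TSV or a data frame
#'   (`sample_id`, `status`).
#' @param interactome Path to a STRING-style edge list or an igraph.
#' @param control A [ppin_control()] list.
#' @return An object of class `ppin_analysis` with components
#'   `control` (resolved parameters), `funnel` (variant-count funnel),
#'   `quality_report`, `deleteriousness_report`, `gtest` (per-variant
#'   results), `seed_genes` (per sample), `networks`, `excluded_samples`,
#'   `distance` (Jaccard matrix), `dendrogram`, `clusters`,
#'   `case_cluster` / `control_cluster` (headline maximal clusters or
#'   `NULL`), `layered` (their layered networks), `unique_genes`, and
#'   `separation`.
#' @export
ppin_analysis <- function(vcf, annotations = NULL, phenotypes, interactome,
                          control = ppin_control()) {
  stopifnot(inherits(control, "ppin_control"))
  variants <- if (inherits(vcf, "ppin_variants")) vcf
    else read_cohort(vcf, annotations)
  phen <- if (is.character(phenotypes)) read_phenotypes(phenotypes)
    else phenotypes[order(phenotypes$sample_id), , drop = FALSE]
  g <- if (inherits(interactome, "igraph")) interactome
    else load_interactome(interactome,
                          confidence_threshold = control$confidence_threshold)

  qf <- quality_filter(variants,
                       density_window = control$density_window,
                       density_count = control$density_count,
                       min_depth = control$min_depth,
                       min_qual = control$min_qual,
                       min_qd = control$min_qd,
                       max_fs = control$max_fs,
                       max_xamb = control$max_xamb)
  df <- deleteriousness_filter(qf$variants,
                               min_polyphen = control$min_polyphen,
                               max_sift = control$max_sift,
                               min_cadd = control$min_cadd,
                               max_maf = control$max_maf)
  survivors <- df$variants
  gt <- gtest_variants(survivors, phen, method = "auto",
                       max_tables = control$max_tables,
                       mc_reps = control$mc_reps, mc_seed = control$mc_seed)

  ids <- phen$sample_id
  networks <- list(); excluded <- character(0)
  seed_sets <- list()
  for (s in ids) {
    seeds <- select_seed_genes(s, survivors, gt, k = control$seed_gene_count)
    seed_sets[[s]] <- seeds
    if (nrow(seeds) == 0L) {
      excluded <- c(excluded, s)
      next
    }
    nw <- tryCatch(
      build_sample_network(seeds, g, sample_id = s,
                           keep_imputed_edges = control$keep_imputed_edges,
                           largest_component = control$largest_component),
      error = function(e) NULL)
    if (is.null(nw)) excluded <- c(excluded, s) else networks[[s]] <- nw
  }
  if (length(networks) < 2L)
    stop("fewer than two samples yield non-empty networks; cannot cluster",
         call. = FALSE)

  dmat <- network_distance_matrix(networks, on = control$jaccard_on)
  dend <- upgma(dmat)
  clusters <- significant_clusters(dend, phen,
                                   min_size = control$min_cluster_size,
                                   alpha = control$alpha,
                                   correction = control$correction)

  # headline cluster per dominance class: the most significant node.
  # (Maximality alone degenerates on strongly structured cohorts: every
  # ancestor of a tight enriched block inherits nominal significance, so the
  # maximal node can balloon toward the root; minimum p stays on the block.)
  pick <- function(which_dom) {
    cand <- clusters[clusters$significant & clusters$dominance == which_dom, ,
                     drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[order(cand$p_value, -cand$size, cand$node)[1L], , drop = FALSE]
  }
  case_cl <- pick("case"); ctrl_cl <- pick("control")
  members_of <- function(cl) {
    if (is.null(cl)) return(NULL)
    dend$members[[cl$node]]
  }
  layered <- list(case = NULL, control = NULL)
  uniq <- NULL; sep <- NULL
  if (!is.null(case_cl))
    layered$case <- build_layered_network(members_of(case_cl), networks)
  if (!is.null(ctrl_cl))
    layered$control <- build_layered_network(members_of(ctrl_cl), networks)
  if (!is.null(layered$case) && !is.null(layered$control)) {
    uniq <- unique_genes(layered$case, layered$control)
    sep <- tryCatch(
      separation_score(uniq$a_only$gene, uniq$b_only$gene, g),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "separation_unavailable"))
  }

  funnel <- data.frame(
    stage = c("input", "quality_pass", "deleterious"),
    n_variants = c(length(variants), length(qf$variants),
                   length(survivors)))

  structure(list(control = control, funnel = funnel,
                 quality_report = qf$report,
                 deleteriousness_report = df$report,
                 variants = survivors, gtest = gt,
                 seed_genes = seed_sets, networks = networks,
                 excluded_samples = excluded,
                 phenotypes = phen, interactome = g,
                 distance = dmat, dendrogram = dend, clusters = clusters,
                 case_cluster = case_cl, control_cluster = ctrl_cl,
                 layered = layered, unique_genes = uniq, separation = sep),
            class = "ppin_analysis")
}

#' @export
print.ppin_analysis <- function(x, ...) {
  cat("ppin_analysis\n")
  cat("  cohort: ", sum(x$phenotypes$status == "case"), " cases / ",
      sum(x$phenotypes$status == "control"), " controls\n", sep = "")
  cat("  variants: ", x$funnel$n_variants[1L], " input -> ",
      x$funnel$n_variants[2L], " quality-pass -> ",
      x$funnel$n_variants[3L], " deleterious\n", sep = "")
  cat("  networks: ", length(x$networks), " samples (",
      length(x$excluded_samples), " excluded)\n", sep = "")
  nsig <- sum(x$clusters$significant)
  cat("  clusters: ", nrow(x$clusters), " tested, ", nsig,
      " significant at alpha = ", x$control$alpha, "\n", sep = "")
  for (nmx in c("case_cluster", "control_cluster")) {
    cl <- x[[nmx]]
    if (!is.null(cl))
      cat("  ", sub("_", "-dominated ", nmx), ": ", cl$n_cases, " cases / ",
          cl$n_controls, " controls, p = ", format(cl$p_value, digits = 3),
          "\n", sep = "")
  }
  if (inherits(x$separation, "separation_result"))
    cat("  separation score (unique case vs control genes): s_AB = ",
        format(x$separation$s_ab, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ppin_analysis <- function(object, ...) {
  print(object)
  cat("\nTested dendrogram nodes:\n")
  print(as.data.frame(object$clusters), row.names = FALSE)
  if (!is.null(object$unique_genes)) {
    cat("\nGenes unique to the case-dominated layered network:\n")
    print(object$unique_genes$a_only, row.names = FALSE)
    cat("\nGenes unique to the control-dominated layered network:\n")
    print(object$unique_genes$b_only, row.names = FALSE)
  }
  invisible(object)
}

#' Plot the patient dendrogram of an analysis
#'
#' Base-graphics dendrogram with case leaves marked in red and control
#' leaves in blue.
#'
#' @param x A `ppin_analysis` object.
#' @param ... Passed to [plot.hclust()].
#' @return `x`, invisibly.
#' @export
plot.ppin_analysis <- function(x, ...) {
  hc <- x$dendrogram$hclust
  plot(hc, labels = FALSE, hang = -1, ylab = "Jaccard distance",
       main = "Patient network clustering (UPGMA)", sub = "", xlab = "", ...)
  st <- x$phenotypes$status[match(hc$labels[hc$order],
                                  x$phenotypes$sample_id)]
  graphics::points(seq_along(st), rep(0, length(st)), pch = 15,
                   col = ifelse(st == "case", "red3", "blue3"), cex = 0.6)
  graphics::legend("topright", legend = c("case", "control"), pch = 15,
                   col = c("red3", "blue3"), bty = "n")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the dendrogram (Newick), the tested-cluster table (TSV + JSON),
#' layered networks (GraphML), unique genes (TSV), the separation result
#' (JSON), and a JSON report with the variant funnel, excluded samples,
#' and the resolved control parameters. Identical analyses produce
#' byte-identical files.
#'
#' @param fit A `ppin_analysis` object.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_ppin_outputs <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$newick <- file.path(dir, "dendrogram.nwk")
  writeLines(newick(fit$dendrogram), paths$newick)

  paths$gtest <- file.path(dir, "genotype_tests.tsv")
  utils::write.table(fit$gtest, paths$gtest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$seed_genes <- file.path(dir, "seed_genes.json")
  jsonlite::write_json(lapply(fit$seed_genes, function(s) s$gene),
                       paths$seed_genes, auto_unbox = FALSE, pretty = TRUE)
  paths$filter_reports <- file.path(dir, "filter_reports.json")
  jsonlite::write_json(list(quality = as.list(fit$quality_report),
                            deleteriousness =
                              as.list(fit$deleteriousness_report)),
                       paths$filter_reports, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  cl <- as.data.frame(fit$clusters)
  paths$clusters_tsv <- file.path(dir, "clusters.tsv")
  utils::write.table(cl, paths$clusters_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$clusters_json <- file.path(dir, "clusters.json")
  jsonlite::write_json(cl, paths$clusters_json, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)

  for (side in c("case", "control")) {
    if (!is.null(fit$layered[[side]])) {
      p <- file.path(dir, paste0("layered_", side, ".graphml"))
      write_network_graphml(fit$layered[[side]], p)
      paths[[paste0("layered_", side)]] <- p
    }
  }
  if (!is.null(fit$unique_genes)) {
    ug <- rbind(cbind(cluster = "case", fit$unique_genes$a_only),
                cbind(cluster = "control", fit$unique_genes$b_only))
    paths$unique_genes <- file.path(dir, "unique_genes.tsv")
    utils::write.table(ug, paths$unique_genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (inherits(fit$separation, "separation_result")) {
    paths$separation <- file.path(dir, "separation.json")
    jsonlite::write_json(lapply(as.list(fit$separation), as.vector),
                         paths$separation, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report <- list(funnel = fit$funnel,
                 quality_filter_counts = as.list(fit$quality_report$counts),
                 deleteriousness_filter_counts =
                   as.list(fit$deleteriousness_report$counts),
                 n_networks = length(fit$networks),
                 excluded_samples = fit$excluded_samples,
                 n_clusters_tested = nrow(fit$clusters),
                 n_clusters_significant = sum(fit$clusters$significant),
                 control = unclass(fit$control))
  paths$report <- file.path(dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
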