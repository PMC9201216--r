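#' Build a 2x3 case/control genotype table for one variant
#'
#' Tallies hom-ref / het / hom-alt genotype counts for cases and controls.
#' Missing genotypes are excluded from the counts and tallied per group.
#'
#' @param genotypes Named integer vector (codes 0/1/2, `NA` missing), names
#'   are sample ids; or a single row of a [ppin_variants] genotype matrix.
#' @param phenotypes Data frame with `sample_id` and `status`
#'   (`case`/`control`) covering every genotyped sample.
#' @return An object of class `genotype_table`: integer matrix with rows
#'   `case`, `control` and columns `hom_ref`, `het`, `hom_alt`, plus an
#'   `n_missing` attribute (named integer, per group).
#' @export
build_genotype_table <- function(genotypes, phenotypes) {
  ids <- names(genotypes)
  if (is.null(ids))
    stop("input error: genotypes must be named by sample id", call. = FALSE)
  st <- phenotypes$status[match(ids, phenotypes$sample_id)]
  if (anyNA(st))
    stop("input error: unlabeled sample(s): ",
         paste(ids[is.na(st)], collapse = ", "), call. = FALSE)
  tab <- matrix(0L, 2L, 3L,
                dimnames = list(c("case", "control"),
                                c("hom_ref", "het", "hom_alt")))
  n_missing <- c(case = 0L, control = 0L)
  for (grp in c("case", "control")) {
    gg <- genotypes[st == grp]
    n_missing[grp] <- sum(is.na(gg))
    cnt <- tabulate(gg + 1L, nbins = 3L)
    tab[grp, ] <- cnt
  }
  structure(tab, n_missing = n_missing, class = c("genotype_table", "matrix"))
}

# log multivariate hypergeometric mass of row-1 counts (a, b, c) given
# column margins cs and row-1 total r1
log_mhyper <- function(a, b, c, cs, r1, n) {
  lchoose(cs[1L], a) + lchoose(cs[2L], b) + lchoose(cs[3L], c) -
    lchoose(n, r1)
}

# enumerate all 2x3 tables with the observed margins; returns row-1 counts
# and their log masses
enum_2x3 <- function(tab) {
  r1 <- sum(tab[1L, ]); cs <- colSums(tab); n <- sum(tab)
  a <- rep(0:min(r1, cs[1L]), each = min(r1, cs[2L]) + 1L)
  b <- rep(0:min(r1, cs[2L]), times = min(r1, cs[1L]) + 1L)
  cc <- r1 - a - b
  keep <- cc >= 0L & cc <= cs[3L] & b <= cs[2L] & a <= cs[1L]
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]
  list(a = a, b = b, c = cc, logp = log_mhyper(a, b, cc, cs, r1, n))
}

#' Exact two-sided Fisher test on a 2x3 genotype table
#'
#' Enumerates every 2x3 table with the observed margins, assigns each its
#' multivariate hypergeometric probability, and sums the probabilities of
#' all tables no more probable than the observed one (relative tolerance
#' 1e-12 for ties). Degenerate margins (an empty row) give p = 1.
#'
#' @param table A 2x3 matrix (e.g. from [build_genotype_table()]).
#' @param max_tables Enumeration cap; an error asks for [fisher_exact_mc()]
#'   if the table space is larger.
#' @return A single p-value in (0, 1].
#' @export
fisher_exact_table <- function(table, max_tables = 1e6) {
  tab <- unclass(table)
  stopifnot(is.matrix(tab), nrow(tab) == 2L, ncol(tab) == 3L)
  if (any(tab < 0)) stop("input error: negative counts", call. = FALSE)
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  if (r1 == 0L || r2 == 0L) return(1)
  size <- (r1 + 1L)^2
  if (size > max_tables)
    stop("enumeration above cap (", size, " candidate tables); ",
         "use fisher_exact_mc()", call. = FALSE)
  en <- enum_2x3(tab)
  lp_obs <- log_mhyper(tab[1L, 1L], tab[1L, 2L], tab[1L, 3L],
                       colSums(tab), r1, sum(tab))
  p <- sum(exp(en$logp[en$logp <= lp_obs + log1p(1e-12)]))
  min(p, 1)
}

#' Monte Carlo Fisher test on a 2x3 genotype table
#'
#' Samples `reps` tables from the fixed-margin null distribution
#' (Patefield's margin-conditioned algorithm, [stats::r2dtable()]) and
#' estimates the two-sided p-value as
#' \eqn{(1 + \#\{P(T_{sim}) \le P(T_{obs})\}) / (reps + 1)}.
#' Deterministic given `seed`. Degenerate margins give p = 1.
#'
#' @param table A 2x3 matrix of counts.
#' @param reps Number of Monte Carlo replicates (at least 1000).
#' @param seed Integer RNG seed, recorded in the result's attributes.
#' @return A p-value in (0, 1] with attributes `mc_reps` and `mc_seed`.
#' @export
fisher_exact_mc <- function(table, reps = 1e5, seed = 1L) {
  tab <- unclass(table)
  stopifnot(is.matrix(tab), nrow(tab) == 2L, ncol(tab) == 3L)
  if (reps < 1000) stop("input error: reps must be >= 1000", call. = FALSE)
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (r[1L] == 0L || r[2L] == 0L)
    return(structure(1, mc_reps = reps, mc_seed = seed))
  set.seed(as.integer(seed))
  sims <- stats::r2dtable(reps, r, cs)
  row1 <- matrix(unlist(sims, use.names = FALSE), nrow = 6L)[c(1L, 3L, 5L), ,
                                                             drop = FALSE]
  lp_sim <- log_mhyper(row1[1L, ], row1[2L, ], row1[3L, ], cs, r[1L], n)
  lp_obs <- log_mhyper(tab[1L, 1L], tab[1L, 2L], tab[1L, 3L], cs, r[1L], n)
  p <- (1 + sum(lp_sim <= lp_obs + log1p(1e-7))) / (reps + 1)
  structure(p, mc_reps = reps, mc_seed = seed)
}

#' Exact two-sided 2x2 Fisher test
#'
#' Sums hypergeometric probabilities of all 2x2 tables with the observed
#' margins that are no more probable than the observed table (relative
#' tolerance 1e-12). All-zero margins give p = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return A p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0))
    stop("input error: negative counts", call. = FALSE)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  d_obs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-12)]))
}

#' Genotype association testing across a variant set
#'
#' Runs the per-variant 2x3 case/control Fisher test for every site. Exact
#' enumeration is used when the table space is within `max_tables`;
#' otherwise the Monte Carlo test. Identical tables share one computation.
#'
#' @param variants A [ppin_variants] object (typically filter survivors).
#' @param phenotypes Phenotype data frame (`sample_id`, `status`).
#' @param method `"auto"` (exact with MC fallback), `"exact"`, or `"mc"`.
#' @param max_tables Enumeration cap for the exact test.
#' @param mc_reps,mc_seed Monte Carlo parameters.
#' @return Data frame with one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `rsid`, `p_value`, `method`, `maf_cases`, `maf_controls`
#'   (cohort alternative-allele frequencies among non-missing genotypes).
#' @export
gtest_variants <- function(variants, phenotypes,
                           method = c("auto", "exact", "mc"),
                           max_tables = 1e6, mc_reps = 1e5, mc_seed = 1L) {
  method <- match.arg(method)
  s <- variants$sites
  g <- variants$geno
  ids <- colnames(g)
  st <- phenotypes$status[match(ids, phenotypes$sample_id)]
  if (anyNA(st))
    stop("input error: unlabeled sample(s): ",
         paste(ids[is.na(st)], collapse = ", "), call. = FALSE)
  n <- nrow(s)
  p <- numeric(n); meth <- character(n)
  maf_ca <- numeric(n); maf_co <- numeric(n)
  cache <- new.env(parent = emptyenv())
  is_case <- st == "case"
  for (i in seq_len(n)) {
    gi <- g[i, ]
    tab <- matrix(c(tabulate(gi[is_case] + 1L, 3L),
                    tabulate(gi[!is_case] + 1L, 3L)),
                  nrow = 2L, byrow = TRUE)
    af <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      sum(x) / (2 * length(x))
    }
    maf_ca[i] <- af(gi[is_case]); maf_co[i] <- af(gi[!is_case])
    key <- paste(tab, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) {
      p[i] <- hit[[1L]]; meth[i] <- hit[[2L]]
      next
    }
    use_exact <- method == "exact" ||
      (method == "auto" && (sum(tab[1L, ]) + 1L)^2 <= max_tables)
    if (use_exact) {
      p[i] <- fisher_exact_table(tab, max_tables = Inf)
      meth[i] <- "exact"
    } else {
      p[i] <- as.numeric(fisher_exact_mc(tab, reps = mc_reps, seed = mc_seed))
      meth[i] <- "monte-carlo"
    }
    cache[[key]] <- list(p[i], meth[i])
  }
  data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
             gene = s$gene, rsid = s$rsid, p_value = p, method = meth,
             maf_cases = maf_ca, maf_controls = maf_co,
             stringsAsFactors = FALSE)
}

#' Select per-sample seed genes
#'
#' For one sample, considers every gene in which that sample carries a
#' het or hom-alt genotype for at least one surviving variant, ranks genes
#' by the minimum genotype-test p-value over that sample's variants in the
#' gene (ties broken lexicographically by gene symbol), and returns the top
#' `k` genes. These seed genes anchor the sample's PPI network.
#'
#' @param sample_id Sample identifier (a genotype column of `variants`).
#' @param variants A [ppin_variants] of surviving variants.
#' @param results Genotype test results from [gtest_variants()] covering the
#'   same sites.
#' @param k Maximum number of seed genes (default 60).
#' @return Data frame `gene`, `p_value`, ordered; zero rows when the sample
#'   carries no qualifying variant. Attribute `sample_id` records the sample.
#' @export
select_seed_genes <- function(sample_id, variants, results, k = 60L) {
  if (!sample_id %in% colnames(variants$geno))
    stop("input error: unknown sample '", sample_id, "'", call. = FALSE)
  if (nrow(results) != nrow(variants$sites))
    stop("input error: results do not cover the variant set", call. = FALSE)
  gi <- variants$geno[, sample_id]
  carrier <- !is.na(gi) & gi >= 1L
  df <- data.frame(gene = variants$sites$gene[carrier],
                   p_value = results$p_value[carrier],
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    pg <- stats::aggregate(p_value ~ gene, data = df, FUN = min)
    pg <- pg[order(pg$p_value, pg$gene), ]
    pg <- utils::head(pg, k)
    rownames(pg) <- NULL
  } else {
    pg <- data.frame(gene = character(0), p_value = numeric(0))
  }
  attr(pg, "sample_id") <- sample_id
  pg
}
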