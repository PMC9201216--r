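#' Site-quality filtering of variant calls
#'
#' Applies the post-calling quality filters to a variant set and reports a
#' per-variant list of failure reasons plus a monotone survivor funnel.
#' A variant is removed when any of the following holds:
#' \itemize{
#'   \item \strong{density}: three or more variants fall within any 10-bp
#'     closed window \eqn{[p, p+10]} on the same chromosome (all members of
#'     such a window fail);
#'   \item \strong{multimapping}: four or more alignments map equally well
#'     (`xamb >= 4`);
#'   \item \strong{depth}: coverage below ten reads (`depth < 10`);
#'   \item \strong{quality}: site quality below 30 (`qual < 30`);
#'   \item \strong{qd}: variant confidence / unfiltered depth below 1.5;
#'   \item \strong{strand_bias}: Phred-scaled strand-bias Fisher p above 200
#'     (`fs > 200`).
#' }
#' All inequalities are strict exactly as stated, so boundary values
#' (depth 10, qual 30, QD 1.5, FS 200, xamb 3) are retained.
#'
#' @param variants A [ppin_variants] object; sorted internally by
#'   (`chrom`, `pos`).
#' @param density_window Window width in bp (closed window `[p, p+window]`).
#' @param density_count Minimum number of variants in a window that triggers
#'   the density filter.
#' @param min_depth,min_qual,min_qd,max_fs,max_xamb Filter thresholds; the
#'   defaults are the standard exome post-calling values described above.
#' @return A list with `variants` (the survivors, a [ppin_variants]) and
#'   `report` (a [filter_report]).
#' @export
quality_filter <- function(variants, density_window = 10L, density_count = 3L,
                           min_depth = 10, min_qual = 30, min_qd = 1.5,
                           max_fs = 200, max_xamb = 3) {
  stopifnot(inherits(variants, "ppin_variants"))
  s <- variants$sites
  if (nrow(s) && (any(s$depth < 0, na.rm = TRUE) ||
                  any(s$qual < 0, na.rm = TRUE)))
    stop("input error: negative depth or quality", call. = FALSE)
  ord <- order(s$chrom, s$pos)
  variants <- subset_variants(variants, ord)
  s <- variants$sites
  n <- nrow(s)

  dens <- logical(n)
  if (n) {
    for (chr in unique(s$chrom)) {
      i_chr <- which(s$chrom == chr)
      p <- s$pos[i_chr]                       # sorted
      j <- 1L
      for (i in seq_along(p)) {
        while (p[i] - p[j] > density_window) j <- j + 1L
        if (i - j + 1L >= density_count)
          dens[i_chr[j:i]] <- TRUE
      }
    }
  }
  fails <- list(density = dens,
                multimapping = !is.na(s$xamb) & s$xamb > max_xamb,
                depth = !is.na(s$depth) & s$depth < min_depth,
                quality = !is.na(s$qual) & s$qual < min_qual,
                qd = !is.na(s$qd) & s$qd < min_qd,
                strand_bias = !is.na(s$fs) & s$fs > max_fs)
  report <- filter_report(fails, variant_keys(variants))
  keep <- !Reduce(`|`, fails)
  list(variants = subset_variants(variants, keep), report = report)
}

#' Deleteriousness filtering of annotated variants
#'
#' Retains exonic variants predicted damaging by all four annotation
#' criteria: PolyPhen-2 HDIV \eqn{\ge 0.957}, SIFT \eqn{< 0.05}, CADD
#' (Phred) \eqn{> 15}, and reference-population minor allele frequency
#' \eqn{< 0.05}. Inequality strictness follows the thresholds exactly, so
#' PolyPhen 0.957 passes while CADD 15 and SIFT 0.05 fail. A variant with
#' any required score missing is removed under the distinct reason
#' `unannotated`.
#'
#' @param variants A [ppin_variants] object.
#' @param min_polyphen,max_sift,min_cadd,max_maf Thresholds as above.
#' @return A list with `variants` (survivors) and `report`
#'   (a [filter_report]).
#' @export
deleteriousness_filter <- function(variants, min_polyphen = 0.957,
                                   max_sift = 0.05, min_cadd = 15,
                                   max_maf = 0.05) {
  stopifnot(inherits(variants, "ppin_variants"))
  s <- variants$sites
  unann <- is.na(s$func) | is.na(s$polyphen2_hdiv) | is.na(s$sift) |
    is.na(s$cadd_phred) | is.na(s$maf_ref)
  ok <- function(x) !is.na(x) & x
  fails <- list(unannotated = unann,
                func = !unann & s$func != "exonic",
                polyphen = !unann & s$polyphen2_hdiv < min_polyphen,
                sift = !unann & s$sift >= max_sift,
                cadd = !unann & s$cadd_phred <= min_cadd,
                maf = !unann & s$maf_ref >= max_maf)
  fails <- lapply(fails, ok)
  report <- filter_report(fails, variant_keys(variants))
  keep <- !Reduce(`|`, fails)
  list(variants = subset_variants(variants, keep), report = report)
}

#' Filter report: per-variant reasons and survivor funnel
#'
#' @param fails Named list of logical vectors (one per filter, in
#'   application order), each marking the variants that fail that filter.
#' @param keys Character vector of variant keys (`chrom:pos:ref:alt`).
#' @return An object of class `filter_report` with elements
#'   `failed_filters` (per-variant character vectors, in filter order),
#'   `counts` (failures per filter), and `funnel` (data frame of the
#'   survivor count after each successive stage; monotone non-increasing).
#' @export
filter_report <- function(fails, keys) {
  stopifnot(is.list(fails), length(names(fails)) == length(fails))
  n <- if (length(fails)) length(fails[[1L]]) else 0L
  fmat <- do.call(cbind, fails)
  per_variant <- lapply(seq_len(n), function(i) names(fails)[fmat[i, ]])
  names(per_variant) <- keys
  cum <- rep(FALSE, n)
  remaining <- integer(length(fails))
  for (i in seq_along(fails)) {
    cum <- cum | fails[[i]]
    remaining[i] <- sum(!cum)
  }
  structure(list(
    failed_filters = per_variant[vapply(per_variant, length, 1L) > 0L],
    counts = vapply(fails, sum, 1L),
    funnel = data.frame(stage = c("input", names(fails)),
                        n_remaining = c(n, remaining))),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}

#' @export
as.list.filter_report <- function(x, ...) {
  list(counts = as.list(x$counts),
       funnel = x$funnel,
       failed_filters = x$failed_filters)
}
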