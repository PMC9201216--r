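#' Annotated variant set
#'
#' Container pairing a per-site table with a genotype matrix. `sites` has
#' one row per biallelic variant site with columns `chrom`, `pos`, `ref`,
#' `alt`, the quality fields `qual`, `depth`, `qd`, `fs`, `xamb`, and the
#' annotation fields `gene`, `func`, `polyphen2_hdiv`, `sift`, `cadd_phred`,
#' `maf_ref`, `rsid`. `geno` is an integer matrix (sites x samples) with
#' diploid codes 0 (hom-ref), 1 (het), 2 (hom-alt) and `NA` for missing.
#'
#' @param sites Data frame of sites as described above.
#' @param geno Integer matrix with one row per site and named sample columns.
#' @return An object of class `ppin_variants`.
#' @export
ppin_variants <- function(sites, geno) {
  stopifnot(is.data.frame(sites), is.matrix(geno),
            nrow(sites) == nrow(geno))
  need <- c("chrom", "pos", "ref", "alt", "gene")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("input error: 'sites' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(colnames(geno)))
    stop("input error: 'geno' must have sample column names", call. = FALSE)
  if (nrow(sites) && any(sites$pos < 1, na.rm = TRUE))
    stop("input error: positions must be >= 1", call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad))
    stop("input error: genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno), class = "ppin_variants")
}

#' @export
print.ppin_variants <- function(x, ...) {
  cat("ppin_variants: ", nrow(x$sites), " sites x ", ncol(x$geno),
      " samples\n", sep = "")
  invisible(x)
}

#' @export
length.ppin_variants <- function(x) nrow(x$sites)

# Row subset preserving site/genotype pairing.
subset_variants <- function(v, keep) {
  ppin_variants(v$sites[keep, , drop = FALSE], v$geno[keep, , drop = FALSE])
}

variant_keys <- function(v) {
  paste(v$sites$chrom, v$sites$pos, v$sites$ref, v$sites$alt, sep = ":")
}

#' Write a multi-sample VCF v4.2 file
#'
#' Site quality fields are carried as INFO keys `DP` (depth), `QD`
#' (quality by depth), `FS` (Phred-scaled strand-bias p) and `XAMB`
#' (count of equally scoring alternative alignments); genotypes as
#' FORMAT `GT` (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param variants A [ppin_variants] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_vcf <- function(variants, path) {
  s <- variants$sites
  g <- variants$geno
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ppinet",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant confidence divided by unfiltered depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias Fisher exact p\">",
           "##INFO=<ID=XAMB,Number=1,Type=Integer,Description=\"Count of equally scoring alternative alignments\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt_str[is.na(gt_str)] <- "./."
  info <- sprintf("DP=%d;QD=%s;FS=%s;XAMB=%d", as.integer(s$depth),
                  format(s$qd, trim = TRUE, scientific = FALSE),
                  format(s$fs, trim = TRUE, scientific = FALSE),
                  as.integer(s$xamb))
  body <- if (nrow(s) == 0L) character(0) else
    paste(s$chrom, s$pos, s$rsid, s$ref, s$alt,
          format(s$qual, trim = TRUE, scientific = FALSE), "PASS", info, "GT",
          apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the variant annotation table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`, `func`,
#' `polyphen2_hdiv`, `sift`, `cadd_phred`, `maf_ref`.
#'
#' @param variants A [ppin_variants] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(variants, path) {
  s <- variants$sites
  out <- data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                    gene = s$gene, func = s$func,
                    polyphen2_hdiv = sprintf("%.10g", s$polyphen2_hdiv),
                    sift = sprintf("%.10g", s$sift),
                    cadd_phred = sprintf("%.10g", s$cadd_phred),
                    maf_ref = sprintf("%.10g", s$maf_ref),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype file
#'
#' @param path TSV with header `sample_id`, `status` (`case` or `control`).
#' @return Data frame with one row per sample, sorted by `sample_id`.
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(p)))
    stop("input error: phenotype file needs 'sample_id' and 'status' columns",
         call. = FALSE)
  bad <- setdiff(unique(p$status), c("case", "control"))
  if (length(bad))
    stop("input error: unknown status value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(p$sample_id))
    stop("input error: duplicated sample ids in phenotype file", call. = FALSE)
  p <- p[order(p$sample_id), c("sample_id", "status")]
  rownames(p) <- NULL
  p
}

#' Read a cohort: VCF + annotation table
#'
#' Parses a multi-sample VCF (via \pkg{vcfR}), joins the per-variant
#' annotation table on (`chrom`, `pos`, `ref`, `alt`), and returns a
#' [ppin_variants] object. Sample columns are ordered alphabetically so that
#' downstream results do not depend on the sample order in the file.
#' Variants with no annotation row keep `NA` scores and are later counted
#' as unannotated by the deleteriousness filter.
#'
#' @param vcf_path Path to a VCF v4.2 file in the dialect of
#'   [write_cohort_vcf()].
#' @param annotation_path Path to the annotation TSV.
#' @return A [ppin_variants] object with sites sorted by (`chrom`, `pos`).
#' @export
read_cohort <- function(vcf_path, annotation_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  num_info <- function(key)
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      depth = num_info("DP"),
                      qd = num_info("QD"),
                      fs = num_info("FS"),
                      xamb = num_info("XAMB"),
                      rsid = fix$ID,
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n)
  geno <- matrix(NA_integer_, nrow = n, ncol = ncol(gt),
                 dimnames = dimnames(gt))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L
  geno <- geno[, order(colnames(geno)), drop = FALSE]
  rownames(geno) <- NULL

  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "func", "polyphen2_hdiv",
            "sift", "cadd_phred", "maf_ref")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("input error: annotation table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  key_v <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  key_a <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  idx <- match(key_v, key_a)
  sites$gene <- ann$gene[idx]
  sites$func <- ann$func[idx]
  sites$polyphen2_hdiv <- ann$polyphen2_hdiv[idx]
  sites$sift <- ann$sift[idx]
  sites$cadd_phred <- ann$cadd_phred[idx]
  sites$maf_ref <- ann$maf_ref[idx]

  ord <- order(sites$chrom, sites$pos)
  ppin_variants(sites[ord, , drop = FALSE], geno[ord, , drop = FALSE])
}
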