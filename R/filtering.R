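#' Filter configuration
#'
#' Thresholds for the variant-to-informative-SNP filter cascade. Defaults are
#' the settings used throughout this package's worked analyses: an indel
#' exclusion distance of 75 bp (one read length), a site QUAL minimum of 20,
#' a per-sample read-depth minimum of 20 and a minor-allele fraction floor of
#' 1%. The optional site prefilter mirrors common GATK hard filters on the
#' INFO fields FS (Fisher strand), QD (quality by depth) and DP (total
#' depth); it is off by default because those filters are usually applied
#' upstream by the variant caller.
#'
#' @param indel_distance SNPs within this many base pairs (inclusive) of an
#'   indel are removed.
#' @param min_qual Minimum site QUAL; missing QUAL fails.
#' @param min_depth Minimum ref+alt read depth for a sample call to be
#'   testable.
#' @param min_minor_fraction Minimum minor-allele read fraction; a call with
#'   `min(ref, alt) / (ref + alt)` strictly below this fails.
#' @param prefilter_fs_max Fail sites with INFO FS above this.
#' @param prefilter_qd_min Fail sites with INFO QD below this.
#' @param prefilter_dp_min Fail sites with INFO DP below this.
#' @param prefilter_enabled Apply the FS/QD/DP prefilter.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(indel_distance = 75, min_qual = 20, min_depth = 20,
                          min_minor_fraction = 0.01,
                          prefilter_fs_max = 30.0, prefilter_qd_min = 2.0,
                          prefilter_dp_min = 100, prefilter_enabled = FALSE) {
  stopifnot(indel_distance >= 0, min_qual >= 0, min_depth >= 0,
            min_minor_fraction >= 0, min_minor_fraction <= 0.5,
            prefilter_fs_max >= 0, prefilter_qd_min >= 0,
            prefilter_dp_min >= 0, is.logical(prefilter_enabled))
  structure(list(indel_distance = indel_distance, min_qual = min_qual,
                 min_depth = min_depth,
                 min_minor_fraction = min_minor_fraction,
                 prefilter_fs_max = prefilter_fs_max,
                 prefilter_qd_min = prefilter_qd_min,
                 prefilter_dp_min = prefilter_dp_min,
                 prefilter_enabled = prefilter_enabled),
            class = "filter_config")
}

# Removal reasons in the order the cascade applies them; a site gets the
# first reason that fires, so accounting is reproducible and partitions the
# input exactly.
filter_reasons <- c("prefilter_fs", "prefilter_qd", "prefilter_dp",
                    "gatk_fail", "indel", "multiallelic", "low_qual",
                    "near_indel", "no_testable_samples")

#' Site-level INFO prefilter (FS / QD / DP)
#'
#' Vectorised check of the optional GATK-style hard filters. A criterion
#' whose INFO field is absent passes; on failure the first violated
#' criterion in the order FS, QD, DP is reported.
#'
#' @param fs,qd,dp Numeric vectors of INFO values (NA where absent).
#' @param cfg A [filter_config()].
#' @return Character vector: `"prefilter_fs"`, `"prefilter_qd"`,
#'   `"prefilter_dp"`, or NA for pass.
#' @export
site_prefilter <- function(fs, qd, dp, cfg = filter_config()) {
  out <- rep(NA_character_, length(fs))
  fail_dp <- !is.na(dp) & dp < cfg$prefilter_dp_min
  fail_qd <- !is.na(qd) & qd < cfg$prefilter_qd_min
  fail_fs <- !is.na(fs) & fs > cfg$prefilter_fs_max
  out[fail_dp] <- "prefilter_dp"
  out[fail_qd] <- "prefilter_qd"
  out[fail_fs] <- "prefilter_fs"
  out
}

#' Classify a site against the variant-level filters
#'
#' Vectorised. Reasons are checked in a fixed order: GATK fail status
#' (FILTER not `PASS`/`.`), indel (any allele longer than one base),
#' multiallelic (more than one ALT), low QUAL (below `min_qual`, or
#' missing). Indel proximity needs neighbourhood context and is handled by
#' [indel_proximity_mask()].
#'
#' @param ref Character vector of REF alleles.
#' @param alt Character vector of comma-joined ALT alleles.
#' @param filter Character vector of FILTER values.
#' @param qual Numeric vector of QUAL values (NA where missing).
#' @param cfg A [filter_config()].
#' @return Character vector of removal reasons, NA for pass.
#' @export
classify_site <- function(ref, alt, filter, qual, cfg = filter_config()) {
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  is_indel <- nchar(ref) != 1L |
    vapply(alt_list, function(a) any(nchar(a) != 1L), logical(1))
  multi <- lengths(alt_list) > 1L
  out <- rep(NA_character_, length(ref))
  out[is.na(qual) | qual < cfg$min_qual] <- "low_qual"
  out[multi] <- "multiallelic"
  out[is_indel] <- "indel"
  out[!(filter %in% c("PASS", "."))] <- "gatk_fail"
  out
}

# TRUE where any allele at the site is longer than one base.
is_indel_site <- function(ref, alt) {
  nchar(ref) != 1L |
    vapply(strsplit(alt, ",", fixed = TRUE),
           function(a) any(nchar(a) != 1L), logical(1))
}

#' Mask SNPs near indels
#'
#' A SNP at position s is masked iff some indel at position i on the same
#' chromosome satisfies `|s - i| <= distance` (inclusive). Indels that fail
#' other filters still mask their neighbours: their local sequence context is
#' equally suspect. Input must be position-sorted within each chromosome.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer positions (1-based).
#' @param is_indel Logical vector flagging indel records.
#' @param distance Window in base pairs (inclusive).
#' @return Logical vector: TRUE where a non-indel site falls inside the
#'   window of some indel. Indel records themselves are never masked (they
#'   are removed as indels).
#' @export
indel_proximity_mask <- function(chrom, pos, is_indel, distance = 75) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(is_indel) == n)
  masked <- logical(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- pos[i]
    if (is.unsorted(p))
      stop(sprintf("positions on chromosome '%s' are not sorted", ch))
    ip <- p[is_indel[i]]
    if (length(ip) == 0L) next
    # number of indels in [p - d, p + d] per site
    hits <- findInterval(p + distance, ip) - findInterval(p - distance - 1, ip)
    masked[i] <- hits > 0L & !is_indel[i]
  }
  masked
}

#' Classify a sample call for testability
#'
#' A call enters the binomial test only when it is a called heterozygote
#' carrying both the reference and the single alternate allele, with enough
#' reads and a minor-allele fraction at or above the floor. Vectorised over
#' calls at biallelic SNP sites.
#'
#' @param gt1,gt2 Integer allele indices (NA = missing genotype).
#' @param ref_count,alt_count Integer read counts from AD.
#' @param cfg A [filter_config()].
#' @return Character vector: NA where testable, otherwise `"no_data"`,
#'   `"homozygous"`, `"low_depth"` or `"low_minor_fraction"`.
#' @export
classify_sample <- function(gt1, gt2, ref_count, alt_count,
                            cfg = filter_config()) {
  n <- length(gt1)
  out <- rep(NA_character_, n)
  tot <- ref_count + alt_count
  minor <- pmin(ref_count, alt_count)
  frac_fail <- !is.na(tot) & tot > 0 & minor / tot < cfg$min_minor_fraction
  out[frac_fail] <- "low_minor_fraction"
  out[!is.na(tot) & tot < cfg$min_depth] <- "low_depth"
  het <- pmin(gt1, gt2) == 0L & pmax(gt1, gt2) == 1L
  out[!is.na(het) & !het] <- "homozygous"
  out[is.na(gt1) | is.na(gt2) | is.na(tot)] <- "no_data"
  out
}

#' Run the full filter cascade and collect informative SNPs
#'
#' Applies, in order: the optional FS/QD/DP prefilter, GATK fail status,
#' indel, multiallelic and QUAL filters, the indel-proximity mask, and the
#' per-sample testability rules. Sites passing everything with at least one
#' testable heterozygous sample are the informative SNPs; each removed site
#' is tallied under exactly one reason so that removed + informative equals
#' the input count.
#'
#' @param vcf An `ase_vcf` from [read_vcf()].
#' @param cfg A [filter_config()].
#' @return An object of class `informative_snps`: list with `sites`
#'   (data.frame chrom, pos, id, ref, alt, qual, key), `samples`, `testable`
#'   (logical matrix), `ref_count` / `alt_count` (integer matrices, NA where
#'   not testable), and `accounting` (data.frame reason / n, with
#'   `informative` and `total` rows appended).
#' @export
collect_informative <- function(vcf, cfg = filter_config()) {
  stopifnot(inherits(vcf, "ase_vcf"))
  s <- vcf$sites
  n <- nrow(s)
  reason <- rep(NA_character_, n)

  base <- classify_site(s$ref, s$alt, s$filter, s$qual, cfg)
  mask <- indel_proximity_mask(s$chrom, s$pos, is_indel_site(s$ref, s$alt),
                               cfg$indel_distance)
  if (cfg$prefilter_enabled) {
    pre <- site_prefilter(s$fs, s$qd, s$dp, cfg)
    reason[!is.na(pre)] <- pre[!is.na(pre)]
  }
  todo <- is.na(reason)
  reason[todo & !is.na(base)] <- base[todo & !is.na(base)]
  todo <- is.na(reason)
  reason[todo & mask] <- "near_indel"

  pass <- which(is.na(reason))
  testable <- matrix(FALSE, n, length(vcf$samples),
                     dimnames = list(NULL, vcf$samples))
  if (length(pass)) {
    g1 <- vcf$gt1[pass, , drop = FALSE]
    g2 <- vcf$gt2[pass, , drop = FALSE]
    rc <- vcf$ref_ad[pass, , drop = FALSE]
    ac <- vcf$alt_ad[pass, , drop = FALSE]
    rc[vcf$missing[pass, , drop = FALSE]] <- NA_integer_
    ac[vcf$missing[pass, , drop = FALSE]] <- NA_integer_
    cls <- classify_sample(as.vector(g1), as.vector(g2),
                           as.vector(rc), as.vector(ac), cfg)
    testable[pass, ] <- is.na(cls)
    none <- pass[rowSums(testable[pass, , drop = FALSE]) == 0L]
    reason[none] <- "no_testable_samples"
  }
  keep <- which(is.na(reason))

  acc_n <- vapply(filter_reasons, function(r) sum(reason == r, na.rm = TRUE),
                  0L)
  accounting <- data.frame(reason = c(filter_reasons, "informative", "total"),
                           n = c(unname(acc_n), length(keep), n),
                           stringsAsFactors = FALSE)

  rc <- vcf$ref_ad[keep, , drop = FALSE]
  ac <- vcf$alt_ad[keep, , drop = FALSE]
  tst <- testable[keep, , drop = FALSE]
  rc[!tst] <- NA_integer_
  ac[!tst] <- NA_integer_
  sites <- s[keep, c("chrom", "pos", "id", "ref", "alt", "qual")]
  rownames(sites) <- NULL
  sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  structure(list(sites = sites, samples = vcf$samples, testable = tst,
                 ref_count = rc, alt_count = ac, accounting = accounting,
                 config = cfg),
            class = "informative_snps")
}

#' Build an informative-SNP set directly from count matrices
#'
#' Constructor for simulation studies and tests: takes per-sample (ref, alt)
#' read-count matrices for already-filtered heterozygous calls (NA marks a
#' non-testable call) and wraps them in the same container
#' [collect_informative()] produces, so the statistical layer can be driven
#' without VCF text.
#'
#' @param ref_count,alt_count Integer matrices, variants x samples; NA marks
#'   a non-testable (sample, variant) pair.
#' @param chrom,pos,ref,alt Optional site annotation vectors; synthesised
#'   when omitted.
#' @return An `informative_snps` object (accounting reflects only the
#'   no-testable-sample drop).
#' @export
informative_counts <- function(ref_count, alt_count,
                               chrom = NULL, pos = NULL,
                               ref = NULL, alt = NULL) {
  ref_count <- as.matrix(ref_count)
  alt_count <- as.matrix(alt_count)
  stopifnot(identical(dim(ref_count), dim(alt_count)))
  n <- nrow(ref_count)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  samples <- colnames(ref_count)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(ref_count)))
  colnames(ref_count) <- colnames(alt_count) <- samples
  tst <- !is.na(ref_count) & !is.na(alt_count)
  keep <- rowSums(tst) > 0L
  sites <- data.frame(chrom = chrom, pos = pos, id = NA_character_,
                      ref = ref, alt = alt, qual = NA_real_,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(sites) <- NULL
  sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  acc <- data.frame(reason = c(filter_reasons, "informative", "total"),
                    n = c(rep(0L, length(filter_reasons) - 1L),
                          sum(!keep), sum(keep), n),
                    stringsAsFactors = FALSE)
  structure(list(sites = sites, samples = samples,
                 testable = tst[keep, , drop = FALSE],
                 ref_count = ref_count[keep, , drop = FALSE],
                 alt_count = alt_count[keep, , drop = FALSE],
                 accounting = acc, config = filter_config()),
            class = "informative_snps")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @export
print.informative_snps <- function(x, ...) {
  cat(sprintf("Informative SNPs: %d variants, %d samples, %d testable calls\n",
              nrow(x$sites), length(x$samples), sum(x$testable)))
  invisible(x)
}
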