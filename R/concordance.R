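# Genotype-set representation shared by the concordance functions: biallelic
# SNP records with genotypes encoded as sorted base pairs ("A/G"), so a
# ref/alt swap between callsets harmonizes automatically.
geno_set <- function(chrom, pos, ref, alt, geno, samples) {
  structure(list(sites = data.frame(chrom = chrom, pos = pos, ref = ref,
                                    alt = alt, stringsAsFactors = FALSE),
                 samples = samples, geno = geno),
            class = "geno_set")
}

# Base-pair genotype strings for biallelic rows of an ase_vcf, NA = missing.
geno_bases <- function(vcf, rows) {
  alleles <- cbind(vcf$sites$ref[rows],
                   sub(",.*$", "", vcf$sites$alt[rows]))
  g1 <- vcf$gt1[rows, , drop = FALSE]
  g2 <- vcf$gt2[rows, , drop = FALSE]
  out <- matrix(NA_character_, length(rows), length(vcf$samples),
                dimnames = list(NULL, vcf$samples))
  ok <- !is.na(g1) & !is.na(g2) & g1 <= 1L & g2 <= 1L
  if (any(ok)) {
    ri <- row(g1)[ok]
    a <- alleles[cbind(ri, g1[ok] + 1L)]
    b <- alleles[cbind(ri, g2[ok] + 1L)]
    out[ok] <- paste(pmin(a, b), pmax(a, b), sep = "/")
  }
  out
}

#' Filter a genotyping-panel VCF for concordance analysis
#'
#' Keeps biallelic SNP records whose genotype call rate among the
#' whitelisted samples is at or above `min_call_rate` (default 97%), and
#' restricts the sample set to the whitelist.
#'
#' @param vcf An `ase_vcf`.
#' @param min_call_rate Minimum fraction of non-missing genotypes.
#' @param samples Character vector of sample names to keep (the overlap with
#'   the other callset); must be non-empty and present in the VCF.
#' @return A `geno_set`.
#' @export
filter_panel_vcf <- function(vcf, min_call_rate = 0.97, samples) {
  stopifnot(inherits(vcf, "ase_vcf"))
  if (missing(samples) || length(samples) == 0L)
    stop("a non-empty sample whitelist is required")
  if (!all(samples %in% vcf$samples))
    stop(sprintf("sample(s) not in VCF: %s",
                 paste(setdiff(samples, vcf$samples), collapse = ", ")))
  j <- match(samples, vcf$samples)
  snp <- !is_indel_site(vcf$sites$ref, vcf$sites$alt) & vcf$sites$n_alts == 1L
  g1 <- vcf$gt1[, j, drop = FALSE]
  g2 <- vcf$gt2[, j, drop = FALSE]
  called <- !is.na(g1) & !is.na(g2)
  rate <- rowMeans(called)
  rows <- which(snp & rate >= min_call_rate)
  sub <- vcf
  sub$samples <- samples
  sub$gt1 <- g1; sub$gt2 <- g2
  geno_set(vcf$sites$chrom[rows], vcf$sites$pos[rows], vcf$sites$ref[rows],
           sub("(,.*)$", "", vcf$sites$alt[rows]),
           geno_bases(sub, rows), samples)
}

#' Filter an RNA-seq VCF for concordance analysis
#'
#' Applies the variant-level rules of the ASE filter cascade — GATK fail
#' status, indels and indel proximity, multiallelic sites, QUAL — and then
#' blanks, per sample, any genotype whose total allelic depth is below the
#' depth threshold, so low-coverage calls never enter a comparison.
#'
#' @param vcf An `ase_vcf`.
#' @param cfg A [filter_config()] (indel distance, QUAL and depth
#'   thresholds are used).
#' @return A `geno_set`.
#' @export
filter_rnaseq_vcf <- function(vcf, cfg = filter_config()) {
  stopifnot(inherits(vcf, "ase_vcf"))
  s <- vcf$sites
  reason <- classify_site(s$ref, s$alt, s$filter, s$qual, cfg)
  near <- indel_proximity_mask(s$chrom, s$pos, is_indel_site(s$ref, s$alt),
                               cfg$indel_distance)
  rows <- which(is.na(reason) & !near)
  geno <- geno_bases(vcf, rows)
  low <- vcf$ad_sum[rows, , drop = FALSE]
  geno[is.na(low) | low < cfg$min_depth] <- NA_character_
  geno_set(s$chrom[rows], s$pos[rows], s$ref[rows], s$alt[rows], geno,
           vcf$samples)
}

#' Genotype concordance matrix between two callsets
#'
#' Intersects two filtered callsets on variant position with compatible
#' allele pairs (a ref/alt swap between files still matches: genotypes are
#' compared as unordered base pairs), then computes percent genotype
#' agreement per sample pair over the sites where both calls are
#' non-missing. `pairing = "matched"` compares samples of the same name;
#' `"all_pairs"` fills the full matrix — the shuffled-control analysis, where
#' off-diagonal entries estimate the chance-agreement floor.
#'
#' @param a,b `geno_set` objects from [filter_panel_vcf()] /
#'   [filter_rnaseq_vcf()].
#' @param pairing `"matched"` (default) or `"all_pairs"`.
#' @return A list of class `concordance_matrix`: `percent` (agreement
#'   matrix, rows = samples of `a`, cols = samples of `b`), `n` (compared
#'   sites per pair), `n_sites` (intersected sites), and for matched pairing
#'   a `matched` data.frame. Print shows mean matched and off-diagonal
#'   concordance.
#' @export
concordance_matrix <- function(a, b, pairing = c("matched", "all_pairs")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(a, "geno_set"), inherits(b, "geno_set"))
  key_a <- paste(a$sites$chrom, a$sites$pos,
                 pmin(a$sites$ref, a$sites$alt),
                 pmax(a$sites$ref, a$sites$alt), sep = ":")
  key_b <- paste(b$sites$chrom, b$sites$pos,
                 pmin(b$sites$ref, b$sites$alt),
                 pmax(b$sites$ref, b$sites$alt), sep = ":")
  ia <- which(key_a %in% key_b)
  ib <- match(key_a[ia], key_b)
  if (length(ia) == 0L) stop("no overlapping SNPs between the two callsets")
  ga <- a$geno[ia, , drop = FALSE]
  gb <- b$geno[ib, , drop = FALSE]
  samples <- if (pairing == "matched") {
    common <- intersect(a$samples, b$samples)
    if (length(common) == 0L) stop("no overlapping samples")
    list(a = common, b = common)
  } else list(a = a$samples, b = b$samples)
  pct <- matrix(NA_real_, length(samples$a), length(samples$b),
                dimnames = list(samples$a, samples$b))
  nn <- matrix(0L, length(samples$a), length(samples$b),
               dimnames = list(samples$a, samples$b))
  for (i in seq_along(samples$a)) {
    gi <- ga[, match(samples$a[i], a$samples)]
    cols <- if (pairing == "matched") i else seq_along(samples$b)
    for (j in cols) {
      gj <- gb[, match(samples$b[j], b$samples)]
      ok <- !is.na(gi) & !is.na(gj)
      nn[i, j] <- sum(ok)
      pct[i, j] <- if (any(ok)) 100 * mean(gi[ok] == gj[ok]) else NA_real_
    }
  }
  matched <- if (pairing == "matched")
    data.frame(sample = samples$a, n = diag(nn), percent = diag(pct),
               stringsAsFactors = FALSE) else NULL
  structure(list(percent = pct, n = nn, n_sites = length(ia),
                 pairing = pairing, matched = matched),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("Genotype concordance over %d intersected SNPs (%s pairing)\n",
              x$n_sites, x$pairing))
  diag_ok <- intersect(rownames(x$percent), colnames(x$percent))
  if (length(diag_ok)) {
    d <- x$percent[cbind(diag_ok, diag_ok)]
    cat(sprintf("  mean matched-sample concordance: %.2f%%\n",
                mean(d, na.rm = TRUE)))
  }
  if (x$pairing == "all_pairs") {
    off <- x$percent
    if (length(diag_ok)) off[cbind(diag_ok, diag_ok)] <- NA
    cat(sprintf("  mean off-diagonal concordance: %.2f%%\n",
                mean(off, na.rm = TRUE)))
  }
  invisible(x)
}
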