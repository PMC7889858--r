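#' ASE frequency per variant with decile binning
#'
#' For each variant in an mdFDR result, the ASE frequency is the number of
#' samples called significant divided by a denominator: either the variant's
#' own testable (biallelic) sample count (default) or the total number of
#' samples in the run. Frequencies are tallied into ten bins over \[0, 1\],
#' left-closed and right-open except the last bin, which is closed (so a
#' frequency of exactly 0.1 falls in 0.1-0.2, and 1.0 in 0.9-1.0).
#'
#' @param mdfdr An `ase_mdfdr` object (or an `ase_fit` containing one).
#' @param denominator `"testable"` (per-variant testable samples, default)
#'   or `"total"` (all samples in the run).
#' @param n_total Total sample count, required for `denominator = "total"`
#'   when `mdfdr` is not an `ase_fit`.
#' @return A list of class `ase_frequency`: `per_variant` (data.frame key,
#'   n_significant, denominator, frequency, bin) and `summary` (data.frame
#'   bin, count, percent).
#' @export
ase_frequency <- function(mdfdr, denominator = c("testable", "total"),
                          n_total = NULL) {
  denominator <- match.arg(denominator)
  if (inherits(mdfdr, "ase_fit")) {
    if (is.null(n_total)) n_total <- length(mdfdr$informative$samples)
    mdfdr <- mdfdr$mdfdr
  }
  stopifnot(inherits(mdfdr, "ase_mdfdr"))
  v <- mdfdr$variants
  den <- if (denominator == "testable") v$k else {
    if (is.null(n_total))
      stop("n_total is required for denominator = \"total\"")
    rep(n_total, nrow(v))
  }
  drop <- den == 0
  if (any(drop)) {
    warning(sprintf("%d variant(s) with zero denominator skipped", sum(drop)),
            call. = FALSE)
    v <- v[!drop, , drop = FALSE]
    den <- den[!drop]
  }
  freq <- v$n_significant / den
  bin_idx <- pmin(floor(freq * 10) + 1L, 10L)   # last bin closed at 1.0
  labs <- sprintf("%.1f-%.1f", seq(0, 0.9, 0.1), seq(0.1, 1, 0.1))
  per_variant <- data.frame(key = v$key, n_significant = v$n_significant,
                            denominator = den, frequency = freq,
                            bin = labs[bin_idx], stringsAsFactors = FALSE)
  counts <- tabulate(bin_idx, nbins = 10L)
  summary <- data.frame(bin = labs, count = counts,
                        percent = if (nrow(v)) 100 * counts / nrow(v)
                                  else rep(0, 10L),
                        stringsAsFactors = FALSE)
  structure(list(per_variant = per_variant, summary = summary,
                 denominator = denominator,
                 n_variants = nrow(v)),
            class = "ase_frequency")
}

#' @export
print.ase_frequency <- function(x, ...) {
  cat(sprintf("ASE frequency over %d variants (denominator: %s)\n",
              x$n_variants, x$denominator))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Direction concordance of significant ASE calls
#'
#' Measures how consistently the significant samples of a variant agree on
#' which allele is the higher-expressed one. Per variant, the majority
#' fraction is `max(#alt_higher, #ref_higher) / #significant`. The global
#' concordance pools significant calls over variants with at least two
#' significant samples (single-sample variants are trivially 100% and would
#' inflate the metric): it is the fraction of pooled significant calls that
#' agree with their variant's majority direction, as a percent.
#'
#' @param mdfdr An `ase_mdfdr` object (or an `ase_fit` containing one).
#' @return A list of class `ase_concordance`: `per_variant` (key,
#'   n_significant, n_alt_higher, n_ref_higher, majority_fraction) and
#'   `global` (percent, NA when no variant has >= 2 significant samples).
#' @export
direction_concordance <- function(mdfdr) {
  if (inherits(mdfdr, "ase_fit")) mdfdr <- mdfdr$mdfdr
  stopifnot(inherits(mdfdr, "ase_mdfdr"))
  s <- mdfdr$samples[mdfdr$samples$significant, , drop = FALSE]
  if (nrow(s) == 0L)
    return(structure(list(per_variant = data.frame(
      key = character(), n_significant = integer(),
      n_alt_higher = integer(), n_ref_higher = integer(),
      majority_fraction = numeric()), global = NA_real_),
      class = "ase_concordance"))
  n_alt <- tapply(s$direction == "alt_higher", s$key, sum)
  n_ref <- tapply(s$direction == "ref_higher", s$key, sum)
  n_sig <- tapply(rep(1L, nrow(s)), s$key, sum)
  keys <- names(n_sig)
  maj <- pmax(n_alt, n_ref) / n_sig
  per_variant <- data.frame(key = keys,
                            n_significant = as.integer(n_sig),
                            n_alt_higher = as.integer(n_alt),
                            n_ref_higher = as.integer(n_ref),
                            majority_fraction = as.numeric(maj),
                            stringsAsFactors = FALSE)
  rownames(per_variant) <- NULL
  multi <- per_variant$n_significant >= 2L
  global <- if (any(multi)) {
    100 * sum(pmax(per_variant$n_alt_higher,
                   per_variant$n_ref_higher)[multi]) /
      sum(per_variant$n_significant[multi])
  } else NA_real_
  structure(list(per_variant = per_variant, global = global),
            class = "ase_concordance")
}

#' @export
print.ase_concordance <- function(x, ...) {
  cat(sprintf("Direction concordance: %.2f%% global (%d variants with >= 2 significant samples)\n",
              x$global, sum(x$per_variant$n_significant >= 2L)))
  invisible(x)
}

#' Mean reference-allele ratio of informative SNPs
#'
#' Mean, over all testable (variant, sample) pairs, of the reference-allele
#' read fraction `ref / (ref + alt)`, reported as a percent. Under unbiased
#' alignment the expectation is 50%; an excess indicates reference-mapping
#' bias (mitigated in practice by masking variant positions in the genome
#' before alignment).
#'
#' @param inf An `informative_snps` object (or an `ase_fit`).
#' @return Mean reference-allele ratio in percent.
#' @export
reference_allele_ratio <- function(inf) {
  if (inherits(inf, "ase_fit")) inf <- inf$informative
  stopifnot(inherits(inf, "informative_snps"))
  t <- inf$testable
  if (!any(t)) stop("no testable (variant, sample) pairs")
  r <- inf$ref_count[t] / (inf$ref_count[t] + inf$alt_count[t])
  100 * mean(r)
}

#' Normalized gene ASE scores
#'
#' Scores each gene by the fraction of its informative SNPs that show ASE:
#' `score = 100 * ase_snps / informative_snps`. Variant-to-gene assignment
#' comes from an annotation table (one row per variant-transcript in
#' VEP-style input is fine; rows are first deduplicated to distinct
#' variant-gene pairs, and a variant mapping to several genes counts once in
#' each).
#'
#' @param annotation data.frame with columns `variant_key`
#'   (`chrom:pos:ref:alt`) and `gene_id` (extra columns ignored).
#' @param informative_keys Character vector of informative variant keys.
#' @param ase_keys Character vector of ASE variant keys; must be a subset of
#'   `informative_keys`.
#' @return A data.frame of class `gene_ase_scores`: gene_id,
#'   informative_snps, ase_snps, score — one row per gene with at least one
#'   informative SNP, sorted by gene_id.
#' @export
gene_ase_scores <- function(annotation, informative_keys, ase_keys) {
  stopifnot(all(c("variant_key", "gene_id") %in% names(annotation)))
  if (!all(ase_keys %in% informative_keys))
    stop("every ASE variant key must also be an informative key")
  pairs <- unique(annotation[c("variant_key", "gene_id")])
  pairs <- pairs[pairs$variant_key %in% informative_keys, , drop = FALSE]
  inf_n <- table(pairs$gene_id)
  ase_n <- table(factor(pairs$gene_id[pairs$variant_key %in% ase_keys],
                        levels = names(inf_n)))
  out <- data.frame(gene_id = names(inf_n),
                    informative_snps = as.integer(inf_n),
                    ase_snps = as.integer(ase_n),
                    stringsAsFactors = FALSE)
  out$score <- 100 * out$ase_snps / out$informative_snps
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_ase_scores", "data.frame")
  out
}

#' Global (cross-tissue) gene ASE scores
#'
#' Averages per-tissue normalized gene ASE scores into a global score: the
#' unweighted mean over the tissues in which the gene has at least one
#' informative SNP. Also reports how many genes clear the 50%, 80% and 100%
#' global-score thresholds.
#'
#' @param score_list Named list of `gene_ase_scores` data.frames, one per
#'   tissue.
#' @return A list of class `global_gene_scores`: `scores` (data.frame
#'   gene_id, n_tissues, global_score) and `thresholds` (named counts for
#'   `ge_50`, `ge_80`, `eq_100`).
#' @export
global_gene_scores <- function(score_list) {
  stopifnot(is.list(score_list), length(score_list) >= 1L)
  all_scores <- do.call(rbind, lapply(score_list, function(d)
    d[c("gene_id", "score")]))
  n_t <- tapply(rep(1L, nrow(all_scores)), all_scores$gene_id, sum)
  gs <- tapply(all_scores$score, all_scores$gene_id, mean)
  scores <- data.frame(gene_id = names(gs),
                       n_tissues = as.integer(n_t[names(gs)]),
                       global_score = as.numeric(gs),
                       stringsAsFactors = FALSE)
  scores <- scores[order(scores$gene_id), , drop = FALSE]
  rownames(scores) <- NULL
  thresholds <- c(ge_50 = sum(scores$global_score >= 50),
                  ge_80 = sum(scores$global_score >= 80),
                  eq_100 = sum(scores$global_score == 100))
  structure(list(scores = scores, thresholds = thresholds),
            class = "global_gene_scores")
}

#' @export
print.global_gene_scores <- function(x, ...) {
  cat(sprintf("Global gene ASE scores for %d genes; >=50%%: %d, >=80%%: %d, =100%%: %d\n",
              nrow(x$scores), x$thresholds["ge_50"], x$thresholds["ge_80"],
              x$thresholds["eq_100"]))
  invisible(x)
}

#' Annotation-category enrichment of ASE variants
#'
#' Tests, per annotation category (VEP-style Impact or Consequence class),
#' whether ASE variants are enriched or depleted relative to informative
#' variants, with a 2x2 Fisher's exact test (category vs all other
#' categories, ASE set vs background). The background is the full
#' informative set by default (the ASE set is a subset of it), or the
#' informative-minus-ASE complement. The fold change is the ratio of the
#' category's percentage in the ASE set to its percentage in the background
#' (Inf when the category occurs only in the ASE set). P-values are BH
#' adjusted across categories.
#'
#' @param annotation data.frame with columns `variant_key` and the grouping
#'   column (`impact` or `consequence`).
#' @param informative_keys,ase_keys Variant key vectors; ASE must be a
#'   subset of informative.
#' @param grouping Name of the annotation column to group by.
#' @param background `"informative"` (default) or `"non_ase"`.
#' @return A data.frame of class `ase_enrichment`: category, n_ase,
#'   pct_ase, n_background, pct_background, fold_change, p, adj_p.
#' @export
annotation_enrichment <- function(annotation, informative_keys, ase_keys,
                                  grouping = c("impact", "consequence"),
                                  background = c("informative", "non_ase")) {
  grouping <- match.arg(grouping)
  background <- match.arg(background)
  stopifnot(all(c("variant_key", grouping) %in% names(annotation)))
  if (!all(ase_keys %in% informative_keys))
    stop("every ASE variant key must also be an informative key")
  ann <- unique(annotation[c("variant_key", grouping)])
  names(ann)[2] <- "category"
  bg_keys <- if (background == "informative") informative_keys
             else setdiff(informative_keys, ase_keys)
  cats <- sort(unique(ann$category))
  ase_tab <- table(factor(ann$category[ann$variant_key %in% ase_keys],
                          levels = cats))
  bg_tab <- table(factor(ann$category[ann$variant_key %in% bg_keys],
                         levels = cats))
  n_ase <- sum(ase_tab)
  n_bg <- sum(bg_tab)
  p <- vapply(seq_along(cats), function(i) {
    tab <- matrix(c(ase_tab[i], n_ase - ase_tab[i],
                    bg_tab[i], n_bg - bg_tab[i]), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  pct_ase <- 100 * as.integer(ase_tab) / n_ase
  pct_bg <- 100 * as.integer(bg_tab) / n_bg
  out <- data.frame(category = cats,
                    n_ase = as.integer(ase_tab), pct_ase = pct_ase,
                    n_background = as.integer(bg_tab),
                    pct_background = pct_bg,
                    fold_change = pct_ase / pct_bg,
                    p = p, adj_p = bh_adjust(p),
                    stringsAsFactors = FALSE)
  attr(out, "grouping") <- grouping
  attr(out, "background") <- background
  class(out) <- c("ase_enrichment", "data.frame")
  out
}

#' Per-variant association of ASE with a binary sample label
#'
#' For each variant, cross-tabulates its testable samples by a binary
#' metadata label (e.g. a phenotype group) against per-sample ASE
#' significance, tests the 2x2 table with Fisher's exact test, and adjusts
#' across variants with Benjamini-Hochberg. Degenerate margins (all samples
#' one label, or no/all significant) give p = 1.
#'
#' @param mdfdr An `ase_mdfdr` object (or an `ase_fit`).
#' @param metadata data.frame with columns `sample` and `label`; every
#'   testable sample must be labelled, and `label` must take at most two
#'   values.
#' @return A data.frame: key, and per label-significance cell counts, p,
#'   adj_p.
#' @export
group_ase_association <- function(mdfdr, metadata) {
  if (inherits(mdfdr, "ase_fit")) mdfdr <- mdfdr$mdfdr
  stopifnot(inherits(mdfdr, "ase_mdfdr"),
            all(c("sample", "label") %in% names(metadata)))
  s <- mdfdr$samples
  lab <- metadata$label[match(s$sample, metadata$sample)]
  if (anyNA(lab))
    stop(sprintf("unlabelled sample(s): %s",
                 paste(unique(s$sample[is.na(lab)]), collapse = ", ")))
  levels <- sort(unique(metadata$label))
  if (length(levels) > 2L) stop("label must be binary")
  if (length(levels) == 1L) levels <- c(levels, paste0(levels, "_other"))
  keys <- unique(s$key)
  res <- t(vapply(keys, function(k) {
    i <- s$key == k
    a_sig <- sum(lab[i] == levels[1] & s$significant[i])
    a_not <- sum(lab[i] == levels[1] & !s$significant[i])
    b_sig <- sum(lab[i] == levels[2] & s$significant[i])
    b_not <- sum(lab[i] == levels[2] & !s$significant[i])
    p <- stats::fisher.test(matrix(c(a_sig, a_not, b_sig, b_not),
                                   nrow = 2))$p.value
    c(a_sig, a_not, b_sig, b_not, p)
  }, numeric(5)))
  out <- data.frame(key = keys,
                    a_significant = as.integer(res[, 1]),
                    a_not = as.integer(res[, 2]),
                    b_significant = as.integer(res[, 3]),
                    b_not = as.integer(res[, 4]),
                    p = res[, 5], adj_p = bh_adjust(res[, 5]),
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- levels
  rownames(out) <- NULL
  out
}
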