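# Build a deterministic mdFDR-like object by driving counts through the
# real procedure: variants skewed enough to be selected produce known
# significant samples.
strong_fixture <- function(directions, depth = 200L) {
  # directions: list per variant of "alt"/"ref" per significant sample;
  # one extra balanced sample per variant stays non-significant.
  n <- length(directions)
  k <- max(lengths(directions)) + 1L
  ref <- alt <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    d <- directions[[i]]
    for (j in seq_along(d)) {
      if (d[j] == "alt") { ref[i, j] <- 5L; alt[i, j] <- depth }
      else { ref[i, j] <- depth; alt[i, j] <- 5L }
    }
    ref[i, length(d) + 1L] <- 30L
    alt[i, length(d) + 1L] <- 30L
  }
  ase_mdfdr(informative_counts(ref, alt), alpha = 0.05)
}

test_that("ASE frequency uses the stated denominator and left-closed decile bins", {
  md <- strong_fixture(list(rep("alt", 3), "alt"))
  fr <- ase_frequency(md, denominator = "testable")
  expect_equal(sum(fr$summary$count), 2L)
  pv <- fr$per_variant
  expect_equal(sort(pv$frequency), c(1 / 2, 3 / 4))
  expect_equal(pv$bin[pv$frequency == 0.75], "0.7-0.8")
  expect_equal(pv$bin[pv$frequency == 0.5], "0.5-0.6")
  # frequency exactly at a bin edge goes right (left-closed convention)
  expect_equal(ase_frequency(md, denominator = "total",
                             n_total = 10)$per_variant$bin,
               rep(c("0.3-0.4", "0.1-0.2"),
                   c(sum(pv$n_significant == 3), sum(pv$n_significant == 1))))
  expect_equal(sum(fr$summary$percent), 100)
})

test_that("15 significant of 23 samples lands in the 0.6-0.7 bin", {
  md <- strong_fixture(list(rep("alt", 15)))
  fr <- ase_frequency(md, denominator = "total", n_total = 23)
  expect_equal(round(fr$per_variant$frequency, 3), 0.652)
  expect_equal(fr$per_variant$bin, "0.6-0.7")
  zero <- strong_fixture(list(rep("alt", 2)))
  zero$samples$significant[] <- FALSE
  zero$variants$n_significant[] <- 0L
  expect_equal(ase_frequency(zero)$per_variant$bin, "0.0-0.1")
})

test_that("frequency bin counts always partition the variant set", {
  sim <- simulate_ase_vcf(sim_config(n_variants = 300, seed = 17))
  fit <- ase_detect(as_ase_vcf(sim))
  fr <- ase_frequency(fit)
  expect_equal(sum(fr$summary$count), nrow(fit$mdfdr$variants))
})

test_that("direction concordance pools variants with two or more significant samples", {
  cc <- direction_concordance(strong_fixture(list(c("alt", "alt", "alt"))))
  expect_equal(cc$per_variant$majority_fraction, 1)
  expect_equal(cc$global, 100)
  cc <- direction_concordance(
    strong_fixture(list(c("alt", "alt", "alt", "ref"))))
  expect_equal(cc$per_variant$majority_fraction, 0.75)
  expect_equal(cc$global, 75)
  # pooling rule: (2 + 1) agreeing of 4 significant = 75%
  cc <- direction_concordance(strong_fixture(list(c("alt", "alt"),
                                                  c("ref", "alt"))))
  expect_equal(cc$global, 100 * (2 + 1) / 4)
  # single-significant-sample variants do not enter the global metric
  cc <- direction_concordance(strong_fixture(list(c("alt", "alt"), "ref")))
  expect_equal(cc$global, 100)
})

test_that("reference allele ratio is 50% for balanced or symmetric counts", {
  inf <- informative_counts(matrix(10L, 3, 2), matrix(10L, 3, 2))
  expect_equal(reference_allele_ratio(inf), 50)
  inf <- informative_counts(rbind(30L, 10L), rbind(10L, 30L))
  expect_equal(reference_allele_ratio(inf), 50)
  inf <- informative_counts(matrix(30L), matrix(10L))
  expect_equal(reference_allele_ratio(inf), 75)
})

test_that("reference allele ratio is invariant under ref/alt label swap of a symmetric fixture", {
  cf <- counts_fixture(400, 8, depth = 50, p_alt = 0.5, seed = 12)
  r1 <- reference_allele_ratio(informative_counts(cf$ref, cf$alt))
  r2 <- reference_allele_ratio(informative_counts(cf$alt, cf$ref))
  expect_equal(r1 + r2, 100, tolerance = 1e-12)
  se <- 100 * stats::sd(cf$ref / 50) / sqrt(length(cf$ref))
  expect_lt(abs(r1 - 50), 3 * se)
})

test_that("gene ASE scores follow (ASE / informative) * 100 per gene", {
  ann <- data.frame(
    variant_key = sprintf("1:%d:A:G", 1:9),
    gene_id = rep(c("g1", "g2", "g3"), c(4, 3, 2)),
    stringsAsFactors = FALSE)
  inf_keys <- ann$variant_key
  ase_keys <- ann$variant_key[c(1, 2, 8, 9)]  # g1: 2 of 4, g2: 0, g3: 2 of 2
  sc <- gene_ase_scores(ann, inf_keys, ase_keys)
  expect_equal(sc$score, c(50, 0, 100))
  expect_equal(sc$informative_snps, c(4L, 3L, 2L))
  # a variant mapping to several genes counts once in each
  multi <- rbind(ann, data.frame(variant_key = "1:1:A:G", gene_id = "g2"))
  sc2 <- gene_ase_scores(multi, inf_keys, ase_keys)
  expect_equal(sc2$informative_snps[sc2$gene_id == "g2"], 4L)
  expect_equal(sc2$score[sc2$gene_id == "g2"], 25)
  expect_error(gene_ase_scores(ann, inf_keys[1:3], ase_keys), "informative")
})

test_that("gene score bounds and monotonicity: removing an ASE SNP never raises a score", {
  ann <- data.frame(variant_key = sprintf("1:%d:A:G", 1:6),
                    gene_id = rep(c("g1", "g2"), each = 3),
                    stringsAsFactors = FALSE)
  full <- gene_ase_scores(ann, ann$variant_key, ann$variant_key[c(1, 2, 4)])
  drop1 <- gene_ase_scores(ann, ann$variant_key, ann$variant_key[c(2, 4)])
  expect_true(all(full$score >= 0 & full$score <= 100))
  expect_true(all(drop1$score <= full$score))
})

test_that("global gene scores average per-tissue scores over covered tissues", {
  mk <- function(g, s) data.frame(gene_id = g, informative_snps = 1L,
                                  ase_snps = 0L, score = s,
                                  stringsAsFactors = FALSE)
  gl <- global_gene_scores(list(t1 = mk(c("g1", "g2"), c(100, 100)),
                                t2 = mk(c("g1", "g2"), c(50, 80)),
                                t3 = mk("g1", 0)))
  expect_equal(gl$scores$global_score[gl$scores$gene_id == "g1"], 50)
  expect_equal(gl$scores$global_score[gl$scores$gene_id == "g2"], 90)
  expect_equal(gl$scores$n_tissues, c(3L, 2L))
  expect_equal(unname(gl$thresholds), c(2L, 1L, 0L))
})

test_that("annotation enrichment computes Fisher 2x2 per category with BH across categories", {
  ann <- data.frame(
    variant_key = sprintf("1:%d:A:G", 1:100),
    impact = rep(c("HIGH", "LOW"), c(20, 80)),
    stringsAsFactors = FALSE)
  inf_keys <- ann$variant_key
  # identical proportions: fold 1, p 1
  en <- annotation_enrichment(ann, inf_keys, inf_keys[c(1:10, 21:60)],
                              grouping = "impact")
  expect_equal(en$fold_change, c(1, 1))
  expect_equal(en$p, c(1, 1))
  # counts reproduce the input set sizes exactly
  expect_equal(sum(en$n_ase), 50L)
  expect_equal(sum(en$n_background), 100L)
  # oracle check on a skewed contrast against the non-ASE background
  ase <- inf_keys[1:20]  # all HIGH
  en2 <- annotation_enrichment(ann, inf_keys, ase, grouping = "impact",
                               background = "non_ase")
  expect_equal(en2$p[en2$category == "HIGH"],
               fisher_oracle(20, 0, 0, 80), tolerance = 1e-9)
  expect_equal(en2$fold_change[en2$category == "HIGH"], Inf)
  expect_equal(en2$adj_p, bh_adjust(en2$p))
})

test_that("a category present only in the ASE set reports Inf fold change with finite p", {
  ann <- data.frame(variant_key = sprintf("1:%d:A:G", 1:10),
                    consequence = rep(c("rare", "common"), c(2, 8)),
                    stringsAsFactors = FALSE)
  en <- annotation_enrichment(ann, ann$variant_key, ann$variant_key[1:2],
                              grouping = "consequence",
                              background = "non_ase")
  row <- en[en$category == "rare", ]
  expect_equal(row$fold_change, Inf)
  expect_true(is.finite(row$p) && row$p <= 1)
})

test_that("group association runs per-variant Fisher tests on label x significance", {
  md <- strong_fixture(list(rep("alt", 6), rep("alt", 2)))
  k <- length(unique(md$samples$sample))
  meta <- data.frame(sample = sort(unique(md$samples$sample)),
                     label = rep(c("A", "B"), length.out = k),
                     stringsAsFactors = FALSE)
  res <- group_ase_association(md, meta)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$adj_p, bh_adjust(res$p))
  # perfectly separated 6-vs-6 table matches the hypergeometric oracle
  expect_equal(fisher_oracle(6, 0, 0, 6), 2 / choose(12, 6),
               tolerance = 1e-12)
  # degenerate margin: all samples one label
  meta1 <- transform(meta, label = "A")
  res1 <- group_ase_association(md, meta1)
  expect_equal(res1$p, rep(1, 2))
  expect_error(group_ase_association(md, meta[-1, ]), "unlabelled")
})
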