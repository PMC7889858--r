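---
title: "Detecting allele-specific expression from multi-sample VCFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific expression from multi-sample VCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelic)
```

## The problem

In a diploid organism, a heterozygous site inside an expressed transcript
lets RNA-seq reads be assigned to the allele they came from. If neither
allele is preferentially expressed, the reads covering the site should split
roughly 50:50 between the reference and alternate alleles; a reproducible
departure from that balance is allele-specific expression (ASE), the
signature of a *cis*-acting regulatory difference (or, more rarely,
imprinting). `allelic` detects ASE directly from a standard multi-sample VCF
produced by an RNA-seq variant-calling workflow: the per-sample AD
("unfiltered allele depth") field already contains the allelic read counts,
so no auxiliary pile-up or haplotype input is needed.

## Filtering to informative SNPs

The statistical model only makes sense for clean biallelic SNPs in called
heterozygotes with adequate coverage, so detection starts with a fixed filter
cascade. Order matters for the bookkeeping: each removed site is counted
under the *first* rule it violates, so the per-reason tallies are mutually
exclusive and sum to the input count exactly — a property the test suite
asserts as an integer identity.

1. *Optional INFO prefilter*: Fisher strand bias FS > 30, quality-by-depth
   QD < 2, total depth DP < 100 (off by default — these hard filters are
   normally applied upstream by the caller; enable them when consuming a raw
   callset).
2. *GATK fail status*: FILTER other than `PASS` or `.`.
3. *Indels*: any allele longer than one base.
4. *Multiallelic sites*: more than one ALT allele.
5. *Low quality*: site QUAL below 20 (missing QUAL fails — the rule is read
   as a variant-level filter, not per-sample genotype quality).
6. *Indel proximity*: SNPs within 75 bp (inclusive, one read length) of any
   indel on the same chromosome. Indels that themselves fail other filters
   still mask their neighbourhood: their local alignment context is equally
   suspect.
7. *Per-sample testability*: a sample enters the test only as a called 0/1
   heterozygote with `ref + alt >= 20` reads and a minor-allele fraction of
   at least 1% (strictly below 1% fails; at a typical depth of 20–100 reads
   the count and fraction readings of a "1% of total counts" rule coincide,
   and the fraction form behaves continuously at high depth).
8. *No testable samples*: sites passing 1–6 with zero testable samples.

Sites surviving with at least one testable sample are the *informative
SNPs*. All thresholds are `filter_config()` parameters; the defaults above
are what every worked example in this package uses.

Two conventions worth making explicit: genotype phasing is ignored
everywhere (only the allele-index multiset matters), and AD is taken
verbatim — it is never re-derived from DP or PL. A record whose FORMAT lacks
AD, or whose AD length contradicts the allele count, keeps its place in the
file but has all calls marked missing, so it falls out as "no testable
samples" rather than being silently skipped at parse time.

## The statistical model

Each testable call is tested against the balanced binomial null. For counts
$(r, a)$ with $n = r + a$, the two-sided exact p-value under
$X \sim \mathrm{Bin}(n, 1/2)$ is

$$p = \min\!\big(1,\; 2\,P(X \ge \max(r, a))\big),$$

which is exact for the symmetric null and equals 1 at perfect balance. No
normal approximation is used at any depth.

Two separate multiple-testing analyses then answer two different questions.

**ASE variants (meta-analysis).** Per variant, the testable samples'
p-values $p_1,\dots,p_k$ are combined with Fisher's method,
$X = -2\sum_i \ln p_i \sim \chi^2_{2k}$ under the null, and the combined
p-values are adjusted across all $m$ informative SNPs with
Benjamini–Hochberg. A variant with adjusted $p \le \alpha$ (default 0.05) is
an ASE variant. This pools evidence across samples and is the natural scale
for downstream gene-level work.

**ASE samples (mdFDR).** To say *which* samples show ASE at a variant — and
in which direction — while still controlling errors at the variant level,
the package uses the canonical two-stage mixed-directional FDR construction
(Guo, Sarkar and Peddada's screen-then-test scheme). Stage 1 computes a
screening p-value per variant and applies BH across the $m$ variants at
$\alpha$, selecting $R$ of them. Stage 2 tests samples only inside selected
variants: sample $j$ of variant $i$ is significant iff

$$p_{ij} \le \frac{\alpha R}{m \, k_i},$$

with direction taken from the observed ordering of the counts (a tie is
impossible for a significant sample at any $\alpha < 1$, since equal counts
give $p = 1$). The default screening statistic is the Šidák-corrected
minimum, $p_i^{\text{screen}} = 1 - (1 - \min_j p_{ij})^{k_i}$, computed
through `log1p`/`expm1` so tiny minima do not lose precision; the Fisher
combined p is available as an alternative (`screen = "fisher"`), since
published descriptions of the two-stage procedure differ in this choice and
the two screens select overlapping but not identical variant sets. The test
suite deliberately asserts only that both results are subsets of the
informative set — the two models answer different questions and their
variant counts need not agree.

### Numerical policy

* Per-sample p-values that underflow to exactly 0 are clamped to the
  smallest positive double before taking logs (with a warning), so the
  Fisher statistic never becomes infinite.
* The chi-square survival function is evaluated in log space, which keeps
  extreme statistics (X beyond ~1400, where the direct tail underflows)
  ordered and positive as long as the result is representable at all.
* BH sorting is stable, so results are deterministic under ties.

## Downstream summaries

* **ASE frequency** (`ase_frequency`): per variant, significant samples
  divided by a denominator — the variant's own testable-sample count by
  default, or the run's total sample count — binned into deciles. Bins are
  left-closed and right-open except the last ([0.9, 1.0] closed), so a
  frequency of exactly 0.1 falls in the 0.1–0.2 bin; both denominators are
  legitimate summaries and both are exposed because the choice changes the
  binning of sparsely covered variants.
* **Direction concordance** (`direction_concordance`): how consistently the
  significant samples of a variant favour the same allele. The global
  figure pools significant calls over variants with at least two
  significant samples; single-sample variants are trivially 100%
  concordant and would inflate the metric, so they are excluded from the
  pooled number (they remain in the per-variant table).
* **Reference-allele ratio** (`reference_allele_ratio`): the mean of
  ref/(ref+alt) over all testable calls, in percent. Its displacement above
  50% measures reference-mapping bias; in practice masking variant
  positions in the reference before alignment moves it back toward 50%.
* **Gene ASE scores** (`gene_ase_scores`, `global_gene_scores`): per gene,
  `100 * (ASE SNPs / informative SNPs)`; the global score is the unweighted
  mean over the tissues where the gene has at least one informative SNP,
  with counts reported at the 50 / 80 / 100% thresholds. A variant
  annotated to several genes counts once in each (VEP-style
  one-row-per-transcript input is deduplicated to variant–gene pairs
  first).
* **Annotation enrichment** (`annotation_enrichment`): per Impact or
  Consequence category, a 2×2 Fisher exact test of the ASE set against a
  background, BH-adjusted across categories. The default background is the
  full informative set — matching the natural "ASE versus informative"
  contrast even though the ASE set is nested in it — with the
  informative-minus-ASE complement available for a disjoint contrast.
* **Group association** (`group_ase_association`): per variant, a Fisher
  exact test of a binary sample label against per-sample significance.

## Genotype concordance between callsets

`filter_panel_vcf` / `filter_rnaseq_vcf` / `concordance_matrix` reimplement
the usual validation of RNA-seq variant calls against an independent
genotyping panel. The panel is filtered to biallelic SNPs with a genotype
call rate of at least 97%; the RNA-seq callset gets the variant-level
cascade (fail status, indels and 75 bp proximity, QUAL ≥ 20) and a
per-sample rule blanking any genotype with fewer than 20 AD reads — the
depth rule is applied per sample rather than per site, consistent with the
testability rule above. Genotypes are compared as unordered base pairs, so
phase, allele order and even a ref/alt swap between the files harmonize
automatically; strand flips are *not* resolved (the intended use shares one
reference build). Matched pairing compares same-named samples; `all_pairs`
fills the full matrix, whose off-diagonal is the chance-agreement floor — a
shuffled-control check that matched concordance is not driven by allele
frequency alone.

## The synthetic study

`simulate_ase_vcf` generates the fixture every stage is validated on: a
seeded, byte-reproducible multi-sample VCF plus a truth table. Heterozygous
calls draw alternate reads from Binomial(depth, 0.7) at planted-ASE
variants and Binomial(depth, 0.5) otherwise; per-call depth is negative
binomial (mean 50, size 5, floored at one read) because RNA-seq coverage is
overdispersed — a Poisson switch exists for closed-form checks. Homozygous
calls carry 1% cross-contamination reads so the minor-allele-fraction
filter path is actually exercised. Contaminant classes (indels, SNPs
planted 40 bp from a companion indel, multiallelic sites, low-QUAL sites,
GATK-failed sites, all-homozygous sites) are assigned in known proportions,
records are spaced 500 bp apart so no *unintended* proximity masking
occurs, and the truth table records the filter outcome the generated data
implies — including the occasional clean site whose draws happen to leave
no testable sample. That makes the truth table an exact oracle for the
filter accounting, not a probabilistic one. `spike_reference_bias` re-draws
heterozygous depths with a chosen reference proportion, emulating the
unmasked-reference condition for the ratio check.

What the generator does *not* emulate: read-level artefacts (mapping
errors, duplicates, position-level coverage correlation along a transcript),
linkage between nearby variants, overdispersion of the allelic fraction
itself (a beta-binomial world where biological replicates share a skew but
individual sites wobble), and genotyping error. Passing tests therefore
demonstrate that the statistics and bookkeeping are correct under the
stated model, not that the binomial is an adequate error model for every
real dataset — at very high depth the pure binomial is known to be
anti-conservative in the presence of unmodelled overdispersion, which is
why the per-sample depth filter and the FDR layers matter in practice.

### Problem sizes used in validation

The suite validates false-discovery control on 200 replicates of a
500-variant × 10-sample null at depth 50, power on 400 variants at skew
0.7 and mean depth 100 with 10 heterozygous samples (recovery of planted
ASE is essentially complete there), bias recovery at a planted 52%
reference proportion, and exact accounting on a 1000-site contaminated
fixture. These sizes give Monte-Carlo standard errors well below the
margins being asserted while keeping the whole suite fast enough to run on
every change.

## Known limitations

* One VCF per run: multi-tissue designs are independent invocations
  combined afterwards (`combine_runs`), mirroring how such studies are
  actually analysed; there is no joint cross-tissue model.
* The binomial null presumes exchangeable reads; no overdispersion
  parameter is fitted.
* Only biallelic SNPs are tested; multiallelic sites are removed rather
  than decomposed.
* The concordance module does not attempt strand-flip inference or
  imputation; it assumes both callsets share a reference build.
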