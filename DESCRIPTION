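Package: allelic
Title: Allele-Specific Expression Detection from Multi-Sample VCF Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects allele-specific expression (ASE) from RNA-seq variant
    calls in standard multi-sample VCF files. Filters variants to informative
    biallelic SNPs (GATK fail status, indels and indel proximity,
    multiallelic sites, quality score, per-sample depth and minor-allele
    fraction), tests each heterozygous sample's allelic read depths against a
    balanced binomial null, calls ASE variants by Fisher's-method
    meta-analysis with Benjamini-Hochberg false discovery rate control, and
    calls ASE samples per variant by a two-stage mixed-directional FDR
    (mdFDR) procedure. Includes downstream summaries (ASE frequency binning,
    direction concordance, reference-allele-ratio bias check, normalized
    gene ASE scores, annotation-category enrichment), a genotype concordance
    matrix between two VCF callsets, and a seeded synthetic VCF generator
    with planted ASE and a ground-truth table for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
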