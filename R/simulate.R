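#' Simulation configuration for synthetic VCF fixtures
#'
#' Describes a synthetic RNA-seq variant callset with planted allele-specific
#' expression and known contaminants, used to validate every stage of the
#' pipeline without external data. Defaults emulate a modest RNA-seq ASE
#' study: overdispersed per-call depth (negative binomial, mean 50, size 5,
#' floored at 1 read), 60% heterozygosity, 10% of clean variants carrying a
#' true alt-allele proportion of 0.7, and small admixtures of indels,
#' near-indel SNPs, multiallelic sites, low-QUAL sites, GATK-failed sites
#' and all-homozygous sites so every filter path is exercised.
#'
#' @param n_variants,n_samples Problem size.
#' @param het_rate Probability a sample is heterozygous at a clean site.
#' @param depth_mean,depth_dispersion Negative-binomial depth model
#'   (dispersion is the `size` parameter; draws below 1 are floored at 1).
#' @param depth_model `"nbinom"` (default) or `"poisson"` (closed-form
#'   checks).
#' @param ase_fraction Fraction of clean variants with a true skew.
#' @param skew True alt-allele read proportion at ASE variants.
#' @param indel_rate,near_indel_rate,multiallelic_rate,low_qual_rate,gatk_fail_rate,all_hom_rate
#'   Contaminant fractions of `n_variants`.
#' @param seed Integer seed; the same configuration always produces
#'   byte-identical VCF text.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 1000, n_samples = 10, het_rate = 0.6,
                       depth_mean = 50, depth_dispersion = 5,
                       depth_model = c("nbinom", "poisson"),
                       ase_fraction = 0.1, skew = 0.7,
                       indel_rate = 0.04, near_indel_rate = 0.03,
                       multiallelic_rate = 0.03, low_qual_rate = 0.03,
                       gatk_fail_rate = 0.04, all_hom_rate = 0.03,
                       seed = 1) {
  rates <- c(het_rate, ase_fraction, indel_rate, near_indel_rate,
             multiallelic_rate, low_qual_rate, gatk_fail_rate, all_hom_rate)
  stopifnot(n_variants >= 1, n_samples >= 1, all(rates >= 0),
            all(rates <= 1), depth_mean > 0, depth_dispersion > 0,
            skew > 0, skew < 1)
  if (sum(indel_rate, near_indel_rate, multiallelic_rate, low_qual_rate,
          gatk_fail_rate, all_hom_rate) > 1)
    stop("contaminant rates sum to more than 1")
  structure(list(n_variants = as.integer(n_variants),
                 n_samples = as.integer(n_samples), het_rate = het_rate,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 depth_model = match.arg(depth_model),
                 ase_fraction = ase_fraction, skew = skew,
                 indel_rate = indel_rate, near_indel_rate = near_indel_rate,
                 multiallelic_rate = multiallelic_rate,
                 low_qual_rate = low_qual_rate,
                 gatk_fail_rate = gatk_fail_rate, all_hom_rate = all_hom_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic VCF with planted ASE and a truth table
#'
#' Draws a multi-sample VCF according to a [sim_config()]. Heterozygous
#' calls draw alternate-allele reads from Binomial(depth, skew) at ASE
#' variants and Binomial(depth, 0.5) at null variants; homozygous calls
#' carry 1% cross-contamination reads so the minor-allele-fraction filter
#' path is exercised. Each near-indel SNP is accompanied by a planted indel
#' record 40 bp away; all other records are spaced 500 bp apart so no
#' unintended proximity masking occurs. The truth table records, per
#' record, its category, its true skew, its per-sample true genotypes, and
#' the filter outcome the generated data implies (`expected_reason`:
#' `informative` for a clean site that generated at least one testable
#' call, otherwise the removal reason) — the oracle for filter accounting.
#'
#' @param cfg A [sim_config()].
#' @param path Optional file path; when given, the VCF text is written there.
#' @return A list of class `ase_sim`: `config`, `samples`, `truth`
#'   (data.frame), `lines` (VCF text), `path` (or NULL), plus the internal
#'   matrices (`gt`, `depth`, `ref_ad`, `alt_ad`, `extra_ad`, `het`) that
#'   [spike_reference_bias()] rewrites.
#' @export
simulate_ase_vcf <- function(cfg = sim_config(), path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    n <- cfg$n_variants
    ns <- cfg$n_samples
    samples <- sprintf("S%02d", seq_len(ns))
    n_of <- function(rate) as.integer(round(rate * n))
    n_con <- c(indel = n_of(cfg$indel_rate),
               near_indel = n_of(cfg$near_indel_rate),
               multiallelic = n_of(cfg$multiallelic_rate),
               low_qual = n_of(cfg$low_qual_rate),
               gatk_fail = n_of(cfg$gatk_fail_rate),
               all_hom = n_of(cfg$all_hom_rate))
    n_clean <- n - sum(n_con)
    if (n_clean < 0) stop("contaminant counts exceed n_variants")
    n_ase <- as.integer(round(cfg$ase_fraction * n_clean))
    if (n_ase > 0 && n_clean == 0)
      stop("ase_fraction > 0 requires at least one clean variant")
    category <- sample(rep(c(names(n_con), "clean_ase", "clean_null"),
                           c(n_con, n_ase, n_clean - n_ase)))
    pos <- seq_len(n) * 500L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    ref[category == "indel"] <- "A"
    alt[category == "indel"] <- "AT"
    is_multi <- category == "multiallelic"
    alt[is_multi] <- vapply(ref[is_multi], function(r)
      paste(sample(setdiff(bases, r), 2L), collapse = ","), "")
    qual <- rep(60, n)
    qual[category == "low_qual"] <- 5
    filt <- rep("PASS", n)
    filt[category == "gatk_fail"] <- "LowQual"

    # genotypes: 0 = hom-ref, 1 = het, 2 = hom-alt
    gt <- matrix(sample(0:2, n * ns, replace = TRUE,
                        prob = c((1 - cfg$het_rate) / 2, cfg$het_rate,
                                 (1 - cfg$het_rate) / 2)), n, ns)
    hom_rows <- category == "all_hom"
    if (any(hom_rows))
      gt[hom_rows, ] <- sample(c(0L, 2L), sum(hom_rows) * ns,
                               replace = TRUE)
    depth <- if (cfg$depth_model == "nbinom")
      matrix(stats::rnbinom(n * ns, size = cfg$depth_dispersion,
                            mu = cfg$depth_mean), n, ns)
    else matrix(stats::rpois(n * ns, cfg$depth_mean), n, ns)
    depth[depth < 1L] <- 1L
    p_alt <- matrix(0.01, n, ns)            # hom-ref contamination floor
    p_alt[gt == 2L] <- 0.99
    het <- gt == 1L
    skew_row <- ifelse(category == "clean_ase", cfg$skew, 0.5)
    p_alt[het] <- skew_row[row(gt)[het]]
    alt_ad <- matrix(stats::rbinom(n * ns, as.vector(depth),
                                   as.vector(p_alt)), n, ns)
    ref_ad <- depth - alt_ad
    # third-allele reads at multiallelic sites: split the alt reads
    extra_ad <- matrix(0L, n, ns)
    if (any(is_multi)) {
      mi <- which(is_multi)
      extra_ad[mi, ] <- matrix(
        stats::rbinom(length(mi) * ns, as.vector(alt_ad[mi, , drop = FALSE]),
                      0.5), length(mi), ns)
      alt_ad[mi, ] <- alt_ad[mi, , drop = FALSE] - extra_ad[mi, , drop = FALSE]
    }

    # companion indel records for near-indel SNPs (40 bp downstream)
    near <- which(category == "near_indel")
    state <- list(chrom = rep("1", n), pos = pos, ref = ref, alt = alt,
                  qual = qual, filter = filt, category = category,
                  gt = gt, depth = depth, ref_ad = ref_ad, alt_ad = alt_ad,
                  extra_ad = extra_ad)
    if (length(near)) {
      ins <- function(x, v) {           # append companion rows, then sort
        if (is.matrix(x)) rbind(x, v) else c(x, v)
      }
      ngt <- matrix(0L, length(near), ns)
      nd <- matrix(30L, length(near), ns)
      state <- list(chrom = ins(state$chrom, rep("1", length(near))),
                    pos = ins(state$pos, pos[near] + 40L),
                    ref = ins(state$ref, rep("A", length(near))),
                    alt = ins(state$alt, rep("AT", length(near))),
                    qual = ins(state$qual, rep(60, length(near))),
                    filter = ins(state$filter, rep("PASS", length(near))),
                    category = ins(state$category,
                                   rep("indel", length(near))),
                    gt = ins(state$gt, ngt), depth = ins(state$depth, nd),
                    ref_ad = ins(state$ref_ad, nd),
                    alt_ad = ins(state$alt_ad, ngt),
                    extra_ad = ins(state$extra_ad, ngt))
      ord <- order(state$pos)
      for (f in names(state)) {
        state[[f]] <- if (is.matrix(state[[f]]))
          state[[f]][ord, , drop = FALSE] else state[[f]][ord]
      }
    }
    sim <- build_sim(state, cfg, samples, path)
    sim
  })
}

# Assemble VCF lines + truth table from simulator state.
build_sim <- function(state, cfg, samples, path) {
  n <- length(state$pos)
  ns <- length(samples)
  min_frac <- filter_config()$min_minor_fraction
  min_depth <- filter_config()$min_depth
  tot <- state$ref_ad + state$alt_ad
  testable <- state$gt == 1L & state$category[row(state$gt)] %in%
    c("clean_null", "clean_ase", "near_indel") &
    tot >= min_depth & pmin(state$ref_ad, state$alt_ad) / tot >= min_frac
  clean <- state$category %in% c("clean_null", "clean_ase")
  expected <- state$category
  expected[state$category == "all_hom"] <- "no_testable_samples"
  expected[clean] <- ifelse(rowSums(testable[clean, , drop = FALSE]) > 0L,
                            "informative", "no_testable_samples")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[state$gt + 1L], n, ns)
  is_multi <- state$category == "multiallelic"
  ad_str <- matrix(paste(state$ref_ad, state$alt_ad, sep = ","), n, ns)
  if (any(is_multi)) {
    mi <- which(is_multi)
    ad_str[mi, ] <- paste(state$ref_ad[mi, , drop = FALSE],
                          state$alt_ad[mi, , drop = FALSE],
                          state$extra_ad[mi, , drop = FALSE], sep = ",")
  }
  dp_str <- state$ref_ad + state$alt_ad + state$extra_ad
  fields <- matrix(paste(gt_str, ad_str, dp_str, sep = ":"), n, ns)
  body <- paste(state$chrom, state$pos, ".", state$ref, state$alt,
                format(state$qual, trim = TRUE), state$filter,
                paste0("DP=", rowSums(dp_str)), "GT:AD:DP",
                apply(fields, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=allelic-simulator",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- c(header, body)
  truth <- data.frame(
    chrom = state$chrom, pos = state$pos, ref = state$ref, alt = state$alt,
    key = variant_key(state$chrom, state$pos, state$ref, state$alt),
    category = state$category,
    true_skew = ifelse(state$category == "clean_ase", cfg$skew,
                       ifelse(state$category == "clean_null", 0.5, NA_real_)),
    expected_reason = expected,
    n_testable = rowSums(testable),
    genotypes = apply(matrix(c("hom_ref", "het", "hom_alt")[state$gt + 1L],
                             n, ns), 1L, paste, collapse = ","),
    stringsAsFactors = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  structure(list(config = cfg, samples = samples, truth = truth,
                 lines = lines, path = path, state = state),
            class = "ase_sim")
}

#' @export
print.ase_sim <- function(x, ...) {
  cat(sprintf("Synthetic VCF: %d records, %d samples (seed %d)\n",
              nrow(x$truth), length(x$samples), x$config$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Re-draw heterozygous depths with a planted reference bias
#'
#' Emulates reference-mapping bias (the situation an unmasked reference
#' genome produces): every heterozygous call's allelic depths are re-drawn
#' with reference-allele proportion `bias` at the same total depth. Null and
#' ASE skews are replaced by the bias, so the expected mean
#' reference-allele ratio of the informative set equals `bias`.
#'
#' @param sim An `ase_sim` from [simulate_ase_vcf()].
#' @param bias Reference-allele proportion in \[0.5, 1).
#' @param path Optional path for the rewritten VCF.
#' @return A new `ase_sim` with re-drawn depths (seeded from the original
#'   seed, offset so it never reuses the generator's stream).
#' @export
spike_reference_bias <- function(sim, bias, path = NULL) {
  stopifnot(inherits(sim, "ase_sim"), bias >= 0.5, bias < 1)
  state <- sim$state
  with_sim_seed(sim$config$seed + 1000003L, {
    het <- state$gt == 1L
    d <- state$ref_ad + state$alt_ad
    state$ref_ad[het] <- stats::rbinom(sum(het), d[het], bias)
    state$alt_ad[het] <- d[het] - state$ref_ad[het]
    build_sim(state, sim$config, sim$samples, path)
  })
}

#' Parse a simulated VCF without touching the file system
#'
#' Convenience bridge from an `ase_sim` to the reader: parses the simulated
#' VCF text exactly as [read_vcf()] would parse the written file.
#'
#' @param sim An `ase_sim`.
#' @return An `ase_vcf`.
#' @export
as_ase_vcf <- function(sim) {
  stopifnot(inherits(sim, "ase_sim"))
  con <- textConnection(sim$lines)
  on.exit(close(con))
  read_vcf(con)
}
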