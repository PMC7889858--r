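#' Exact two-sided binomial test for allelic balance
#'
#' Tests per-sample allelic read counts against the balanced null
#' Binomial(n, 0.5). Under a symmetric null the two-sided p-value reduces to
#' `min(1, 2 * P(X >= max(ref, alt)))`, computed exactly (no normal
#' approximation at any depth). Perfectly balanced counts give p = 1.
#'
#' @param ref_count,alt_count Non-negative integer vectors of reference- and
#'   alternate-allele read counts (recycled to a common length).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' binom_ase_p(10, 10)   # 1
#' binom_ase_p(15, 5)    # 0.04139...
#' @export
binom_ase_p <- function(ref_count, alt_count) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  n <- ref_count + alt_count
  if (any(n < 1, na.rm = TRUE))
    stop("at least one read is required (ref_count + alt_count >= 1)")
  hi <- pmax(ref_count, alt_count)
  p <- 2 * stats::pbinom(hi - 1, n, 0.5, lower.tail = FALSE)
  pmin(p, 1)
}

#' Combine p-values by Fisher's method
#'
#' Combines k independent p-values into the statistic `X = -2 * sum(log p)`,
#' referred to the upper tail of a chi-square distribution with 2k degrees of
#' freedom. With k = 1 the combined p equals the input p. Zero p-values
#' (possible only through floating-point underflow upstream) are clamped to
#' the smallest positive double with a warning.
#'
#' @param pvalues Numeric vector of p-values in (0, 1]; must be non-empty.
#' @param clamp Replacement value for underflowed zeros.
#' @return A list with `statistic` (X), `df` (2k) and `p` (combined p-value).
#' @examples
#' fisher_combine(c(0.5, 0.5))$p  # 0.59657
#' @export
fisher_combine <- function(pvalues, clamp = .Machine$double.xmin) {
  if (length(pvalues) == 0L) stop("fisher_combine needs at least one p-value")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (any(pvalues == 0)) {
    warning("p-value of 0 clamped to smallest positive double", call. = FALSE)
    pvalues[pvalues == 0] <- clamp
  }
  x <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = x, df = df, p = chisq_sf(x, df))
}

# Chi-square survival function; log-space evaluation keeps extreme
# statistics (X > ~1400, where the direct tail underflows) meaningful.
chisq_sf <- function(x, df) {
  exp(stats::pchisq(x, df, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`p_(i) * m / i` with monotone enforcement, capped
#' at 1), returned in the input order. Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

# Per-sample binomial p-value matrix for an informative set; NA where not
# testable. Underflowed zeros are clamped so Fisher's log never hits -Inf.
sample_p_matrix <- function(inf) {
  p <- matrix(NA_real_, nrow(inf$ref_count), ncol(inf$ref_count),
              dimnames = dimnames(inf$ref_count))
  t <- inf$testable
  if (any(t)) p[t] <- binom_ase_p(inf$ref_count[t], inf$alt_count[t])
  if (any(p[t] == 0)) p[t][p[t] == 0] <- .Machine$double.xmin
  p
}

#' Meta-analysis of ASE across samples (ASE variants)
#'
#' For each informative SNP, combines the testable samples' binomial
#' p-values with Fisher's method and adjusts the combined p-values across
#' all informative SNPs with Benjamini-Hochberg. A variant is called ASE
#' when its adjusted p-value is at or below `alpha`.
#'
#' @param inf An `informative_snps` object.
#' @param alpha FDR level (default 0.05).
#' @return A data.frame of class `ase_meta`: chrom, pos, ref, alt, key, k,
#'   fisher_X, combined_p, adj_p, is_ase.
#' @export
ase_meta <- function(inf, alpha = 0.05) {
  stopifnot(inherits(inf, "informative_snps"), alpha > 0, alpha < 1)
  if (nrow(inf$sites) == 0L) stop("no informative SNPs to test")
  p <- sample_p_matrix(inf)
  k <- rowSums(inf$testable)
  lp <- log(p)
  lp[!inf$testable] <- 0
  x <- -2 * rowSums(lp)
  combined <- chisq_sf(x, 2 * k)
  adj <- bh_adjust(combined)
  out <- data.frame(inf$sites[c("chrom", "pos", "ref", "alt", "key")],
                    k = k, fisher_X = x, combined_p = combined,
                    adj_p = adj, is_ase = adj <= alpha,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("ase_meta", "data.frame")
  out
}

#' Two-stage mdFDR procedure (ASE samples per variant)
#'
#' Identifies, with mixed-directional FDR control, the individual samples
#' that show ASE at each variant. Stage 1 screens variants: each variant's
#' screening p-value (by default the Sidak-corrected minimum of its samples'
#' p-values, `1 - (1 - min p)^k`; alternatively the Fisher combined p) is
#' adjusted by Benjamini-Hochberg across the m informative variants, and
#' variants with adjusted p at or below `alpha` are selected (R of m).
#' Stage 2 tests samples only within selected variants: sample j of variant
#' i is significant iff `p_ij <= alpha * R / (m * k_i)`, and its direction
#' is taken from the sign of alt - ref. Non-selected variants have no
#' significant samples.
#'
#' @param inf An `informative_snps` object.
#' @param alpha mdFDR level (default 0.05).
#' @param screen Screening statistic: `"sidak_min"` (default) or `"fisher"`.
#' @return A list of class `ase_mdfdr` with
#'   \describe{
#'     \item{variants}{data.frame: key, chrom, pos, ref, alt, k, screen_p,
#'       adj_screen_p, selected, n_significant}
#'     \item{samples}{long data.frame over testable calls: key, sample,
#'       ref_count, alt_count, p, significant, direction}
#'     \item{R, m, alpha, screen}{procedure bookkeeping}
#'   }
#' @export
ase_mdfdr <- function(inf, alpha = 0.05,
                      screen = c("sidak_min", "fisher")) {
  stopifnot(inherits(inf, "informative_snps"), alpha > 0, alpha < 1)
  screen <- match.arg(screen)
  if (nrow(inf$sites) == 0L) stop("no informative SNPs to test")
  p <- sample_p_matrix(inf)
  k <- rowSums(inf$testable)
  m <- nrow(inf$sites)
  if (screen == "sidak_min") {
    pmin_i <- suppressWarnings(apply(p, 1L, min, na.rm = TRUE))
    screen_p <- -expm1(k * log1p(-pmin_i))
  } else {
    lp <- log(p); lp[!inf$testable] <- 0
    screen_p <- chisq_sf(-2 * rowSums(lp), 2 * k)
  }
  adj <- bh_adjust(screen_p)
  selected <- adj <= alpha
  R <- sum(selected)
  thr <- alpha * R / (m * k)          # per-variant stage-2 threshold
  sig <- inf$testable & sweep(p, 1L, thr, `<=`) & selected
  dir <- matrix(NA_character_, nrow(p), ncol(p))
  dir[inf$testable] <- ifelse(
    inf$alt_count[inf$testable] > inf$ref_count[inf$testable], "alt_higher",
    ifelse(inf$ref_count[inf$testable] > inf$alt_count[inf$testable],
           "ref_higher", "tie"))
  idx <- which(inf$testable, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  samples_df <- data.frame(
    key = inf$sites$key[idx[, 1]],
    sample = inf$samples[idx[, 2]],
    ref_count = inf$ref_count[idx],
    alt_count = inf$alt_count[idx],
    p = p[idx],
    significant = sig[idx],
    direction = dir[idx],
    stringsAsFactors = FALSE)
  variants_df <- data.frame(
    inf$sites[c("key", "chrom", "pos", "ref", "alt")],
    k = k, screen_p = screen_p, adj_screen_p = adj, selected = selected,
    n_significant = rowSums(sig), stringsAsFactors = FALSE)
  structure(list(variants = variants_df, samples = samples_df,
                 R = R, m = m, alpha = alpha, screen = screen),
            class = "ase_mdfdr")
}

#' @export
print.ase_mdfdr <- function(x, ...) {
  cat(sprintf(
    "mdFDR: %d of %d variants selected (alpha = %g, screen = %s); %d significant sample calls\n",
    x$R, x$m, x$alpha, x$screen, sum(x$samples$significant)))
  invisible(x)
}

#' Detect allele-specific expression in a VCF
#'
#' The main entry point: filters a multi-sample VCF to informative biallelic
#' SNPs and runs one or both statistical analyses — the Fisher's-method
#' meta-analysis calling ASE *variants*, and the two-stage mdFDR procedure
#' calling ASE *samples* per variant with direction.
#'
#' @param x A path to a VCF file, an `ase_vcf` object, or an
#'   `informative_snps` object (already-filtered counts).
#' @param cfg A [filter_config()]; ignored when `x` is already informative.
#' @param alpha FDR level for both analyses (default 0.05).
#' @param model `"both"` (default), `"meta"` or `"mdfdr"`.
#' @param screen Screening statistic for the mdFDR stage 1 (see
#'   [ase_mdfdr()]).
#' @return An object of class `ase_fit`: list with `informative`,
#'   `accounting`, `meta` (or NULL), `mdfdr` (or NULL), `alpha`, `config`,
#'   `model`, `call`. Has `print`, `summary` and `plot` methods.
#' @examples
#' sim <- simulate_ase_vcf(sim_config(n_variants = 50, seed = 11))
#' fit <- ase_detect(as_ase_vcf(sim))
#' summary(fit)
#' @export
ase_detect <- function(x, cfg = filter_config(), alpha = 0.05,
                       model = c("both", "meta", "mdfdr"),
                       screen = c("sidak_min", "fisher")) {
  model <- match.arg(model)
  screen <- match.arg(screen)
  if (is.character(x)) x <- read_vcf(x)
  inf <- if (inherits(x, "informative_snps")) x
         else collect_informative(x, cfg)
  fit <- list(
    informative = inf,
    accounting = inf$accounting,
    meta = if (model %in% c("both", "meta")) ase_meta(inf, alpha) else NULL,
    mdfdr = if (model %in% c("both", "mdfdr"))
      ase_mdfdr(inf, alpha, screen) else NULL,
    alpha = alpha, config = inf$config, model = model,
    call = match.call())
  class(fit) <- "ase_fit"
  fit
}

#' @export
print.ase_fit <- function(x, ...) {
  cat("Allele-specific expression fit\n")
  tot <- x$accounting$n[x$accounting$reason == "total"]
  cat(sprintf("  sites: %d total, %d informative\n", tot,
              nrow(x$informative$sites)))
  if (!is.null(x$meta))
    cat(sprintf("  meta-analysis: %d ASE variants (BH-FDR, alpha = %g)\n",
                sum(x$meta$is_ase), x$alpha))
  if (!is.null(x$mdfdr))
    cat(sprintf("  mdFDR: %d variants selected, %d significant sample calls\n",
                x$mdfdr$R, sum(x$mdfdr$samples$significant)))
  invisible(x)
}

#' @export
summary.ase_fit <- function(object, ...) {
  inf <- object$informative
  out <- list(
    accounting = object$accounting,
    n_informative = nrow(inf$sites),
    n_samples = length(inf$samples),
    n_testable_calls = sum(inf$testable),
    reference_allele_ratio = reference_allele_ratio(inf),
    alpha = object$alpha,
    n_ase_variants = if (!is.null(object$meta)) sum(object$meta$is_ase)
                     else NA_integer_,
    n_mdfdr_selected = if (!is.null(object$mdfdr)) object$mdfdr$R
                       else NA_integer_,
    n_significant_calls = if (!is.null(object$mdfdr))
      sum(object$mdfdr$samples$significant) else NA_integer_)
  class(out) <- "summary.ase_fit"
  out
}

#' @export
print.summary.ase_fit <- function(x, ...) {
  cat("Filter accounting (sites):\n")
  print(x$accounting, row.names = FALSE)
  cat(sprintf("\nInformative SNPs: %d across %d samples (%d testable calls)\n",
              x$n_informative, x$n_samples, x$n_testable_calls))
  cat(sprintf("Mean reference-allele ratio: %.2f%%\n",
              x$reference_allele_ratio))
  if (!is.na(x$n_ase_variants))
    cat(sprintf("ASE variants (meta-analysis, alpha = %g): %d (%.2f%%)\n",
                x$alpha, x$n_ase_variants,
                100 * x$n_ase_variants / x$n_informative))
  if (!is.na(x$n_mdfdr_selected))
    cat(sprintf("mdFDR-selected variants: %d; significant sample calls: %d\n",
                x$n_mdfdr_selected, x$n_significant_calls))
  invisible(x)
}

#' @export
plot.ase_fit <- function(x, which = c("pvalues", "ratio"), ...) {
  which <- match.arg(which)
  if (which == "pvalues") {
    if (is.null(x$meta)) stop("fit has no meta-analysis component")
    graphics::hist(x$meta$combined_p, breaks = 20,
                   main = "Fisher combined p-values",
                   xlab = "combined p", ...)
  } else {
    inf <- x$informative
    r <- inf$ref_count[inf$testable] /
      (inf$ref_count[inf$testable] + inf$alt_count[inf$testable])
    graphics::hist(r, breaks = 30,
                   main = "Reference-allele read fraction (testable calls)",
                   xlab = "ref / (ref + alt)", ...)
    graphics::abline(v = 0.5, lty = 2)
  }
  invisible(x)
}
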