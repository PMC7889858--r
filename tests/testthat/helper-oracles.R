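# Independent oracles and fixture builders used across the suite.

# Brute-force two-sided binomial p at p0 = 0.5: enumerate the pmf as
# choose(n, x) / 2^n and sum both tails at least as extreme as observed.
binom_oracle <- function(ref, alt) {
  n <- ref + alt
  hi <- max(ref, alt)
  if (ref == alt) return(1)
  min(1, 2 * sum(choose(n, hi:n)) / 2^n)
}

# Quadratic-time BH reference: adj_i = min over j with p_j >= p_i of
# min(1, m * p_j / rank(p_j)), rank = number of p-values <= p_j.
bh_oracle <- function(p) {
  m <- length(p)
  rank_max <- vapply(p, function(x) sum(p <= x), 0L)
  cand <- pmin(1, m * p / rank_max)
  vapply(seq_len(m), function(i) min(cand[p >= p[i]]), numeric(1))
}

# Hypergeometric enumeration for the two-sided Fisher exact test of a 2x2
# table [[a, b], [c, d]] (row margins a+b, c+d fixed).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Minimal VCF fixture builders.
vcf_record <- function(pos, ref = "A", alt = "G", qual = "50",
                       filter = "PASS", info = ".", fmt = "GT:AD",
                       calls = "0/1:25,25", chrom = "1", id = ".") {
  paste(c(chrom, pos, id, ref, alt, qual, filter, info, fmt, calls),
        collapse = "\t")
}

vcf_text <- function(records, samples = "S01") {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

read_vcf_text <- function(lines, ...) {
  con <- textConnection(lines)
  on.exit(close(con))
  read_vcf(con, ...)
}

# Null / skewed count matrices for the statistical layer (fixed depth).
counts_fixture <- function(n_variants, n_samples, depth, p_alt, seed) {
  set.seed(seed)
  alt <- matrix(rbinom(n_variants * n_samples, depth, p_alt),
                n_variants, n_samples)
  list(ref = depth - alt, alt = alt)
}
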