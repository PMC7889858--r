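test_that("binomial test matches enumeration and stats::binom.test", {
  expect_equal(binom_ase_p(10, 10), 1)
  expect_equal(binom_ase_p(15, 5), 2 * 21700 / 2^20, tolerance = 1e-12)
  expect_equal(binom_ase_p(20, 0), 2 / 2^20, tolerance = 1e-12)
  # spot-check against the independent routine in base R
  for (cnt in list(c(30, 12), c(3, 17), c(55, 45), c(1, 0)))
    expect_equal(binom_ase_p(cnt[1], cnt[2]),
                 stats::binom.test(cnt[1], sum(cnt), 0.5)$p.value,
                 tolerance = 1e-12)
  expect_error(binom_ase_p(-1, 5), "non-negative")
  expect_error(binom_ase_p(0, 0), "at least one read")
})

test_that("Fisher combination: identity at k = 1, closed form at k = 2, zero statistic", {
  set.seed(1)
  for (p in runif(50)) expect_equal(fisher_combine(p)$p, p, tolerance = 1e-12)
  f <- fisher_combine(c(0.5, 0.5))
  expect_equal(f$statistic, -2 * 2 * log(0.5), tolerance = 1e-12)
  # chi-square(4) survival closed form: exp(-x/2) * (1 + x/2)
  expect_equal(f$p, exp(-f$statistic / 2) * (1 + f$statistic / 2),
               tolerance = 1e-12)
  expect_equal(round(f$p, 5), 0.59657)
  expect_equal(fisher_combine(c(1, 1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p, 1)
  # permutation invariance of the statistic
  set.seed(2)
  p <- runif(7)
  expect_equal(fisher_combine(p)$statistic,
               fisher_combine(rev(p))$statistic, tolerance = 1e-12)
  expect_warning(f0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_gt(f0$statistic, 0)
  expect_error(fisher_combine(numeric(0)), "at least one")
})

test_that("extreme Fisher statistics stay positive through log-space evaluation", {
  p <- rep(1e-31, 10)                     # X ~ 1427, past naive underflow
  f <- fisher_combine(p)
  expect_gt(f$statistic, 1400)
  expect_gt(f$p, 0)
  expect_lt(f$p, 1e-250)
})

test_that("BH adjustment matches hand-worked examples and restores input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02))
})

test_that("BH adjustment matches a quadratic-time reference on random vectors", {
  set.seed(99)
  for (i in 1:300) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("meta-analysis composes the binomial, Fisher and BH pieces", {
  inf <- informative_counts(matrix(10L), matrix(10L))
  m <- ase_meta(inf)
  expect_equal(m$combined_p, 1)
  expect_false(m$is_ase)
  inf <- informative_counts(matrix(20L), matrix(0L))
  m <- ase_meta(inf)
  expect_equal(m$adj_p, 2 / 2^20, tolerance = 1e-12)  # m = 1: BH identity
  expect_true(m$is_ase)
  expect_equal(m$k, 1)
  # BH is applied across all informative variants
  cf <- counts_fixture(50, 4, depth = 40, p_alt = 0.5, seed = 5)
  inf <- informative_counts(cf$ref, cf$alt)
  m <- ase_meta(inf)
  expect_equal(m$adj_p, bh_adjust(m$combined_p))
  expect_true(all(m$adj_p >= m$combined_p))
  expect_equal(m$fisher_X >= 0, rep(TRUE, 50))
})

test_that("mdFDR collapses to the plain threshold when m = k = 1", {
  # p = 0.04 at alpha 0.05: selected and significant
  inf <- informative_counts(matrix(33L), matrix(15L))  # p ~ 0.0131
  r <- ase_mdfdr(inf, alpha = 0.05)
  expect_true(r$variants$selected)
  expect_true(r$samples$significant)
  expect_equal(r$samples$direction, "ref_higher")
  # p above alpha: not selected, no significant samples
  inf <- informative_counts(matrix(30L), matrix(18L))  # p ~ 0.1
  r <- ase_mdfdr(inf, alpha = 0.05)
  expect_false(r$variants$selected)
  expect_false(any(r$samples$significant))
})

test_that("mdFDR stage-2 threshold is alpha * R / (m * k) within selected variants", {
  # two variants, two samples each: one strongly skewed, one null
  ref <- rbind(c(40L, 38L), c(20L, 21L))
  alt <- rbind(c(2L, 3L), c(20L, 19L))
  r <- ase_mdfdr(informative_counts(ref, alt), alpha = 0.05)
  expect_equal(r$m, 2L)
  expect_equal(r$R, 1L)
  thr <- 0.05 * r$R / (r$m * 2)
  s1 <- r$samples[r$samples$key == r$variants$key[1], ]
  expect_equal(s1$significant, s1$p <= thr)
  expect_true(all(s1$direction == "ref_higher"))
  s2 <- r$samples[r$samples$key == r$variants$key[2], ]
  expect_false(any(s2$significant))
})

test_that("significant-call count is monotone non-increasing as alpha tightens", {
  cf <- counts_fixture(80, 6, depth = 60, p_alt = 0.65, seed = 21)
  inf <- informative_counts(cf$ref, cf$alt)
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  sig <- vapply(alphas, function(a)
    sum(ase_mdfdr(inf, alpha = a)$samples$significant), 0)
  expect_true(all(diff(sig) <= 0))
})

test_that("both screening statistics select subsets of the informative set that need not agree", {
  set.seed(4)
  alt <- matrix(rbinom(200 * 5, 50, rep(sample(c(0.5, 0.68), 200, TRUE,
                                               prob = c(.7, .3)), 5)), 200, 5)
  inf <- informative_counts(50L - alt, alt)
  meta <- ase_meta(inf)
  md_s <- ase_mdfdr(inf, screen = "sidak_min")
  md_f <- ase_mdfdr(inf, screen = "fisher")
  keys <- inf$sites$key
  expect_true(all(meta$key[meta$is_ase] %in% keys))
  expect_true(all(md_s$variants$key[md_s$variants$selected] %in% keys))
  expect_true(all(md_f$variants$key[md_f$variants$selected] %in% keys))
  # Fisher screening reuses the meta-analysis combined p per variant
  expect_equal(md_f$variants$screen_p, meta$combined_p, tolerance = 1e-12)
})

test_that("meta-analysis power rises with depth and with distance from balance", {
  power_at <- function(depth, p_alt, seed) {
    cf <- counts_fixture(150, 8, depth, p_alt, seed)
    mean(ase_meta(informative_counts(cf$ref, cf$alt))$is_ase)
  }
  expect_lte(power_at(30, 0.55, 8), power_at(120, 0.55, 8) + 0.02)
  expect_lte(power_at(50, 0.55, 9), power_at(50, 0.70, 9) + 0.02)
})

test_that("ase_detect wires filtering and both models into one fit object", {
  sim <- simulate_ase_vcf(sim_config(n_variants = 200, seed = 3))
  fit <- ase_detect(as_ase_vcf(sim))
  expect_s3_class(fit, "ase_fit")
  expect_identical(fit$meta$key, fit$informative$sites$key)
  expect_true(all(fit$mdfdr$samples$key %in% fit$informative$sites$key))
  out <- capture.output(print(fit))
  expect_match(out[1], "Allele-specific expression fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.ase_fit")
  expect_equal(s$n_informative, nrow(fit$informative$sites))
  meta_only <- ase_detect(as_ase_vcf(sim), model = "meta")
  expect_null(meta_only$mdfdr)
  expect_equal(meta_only$meta, fit$meta)
})
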