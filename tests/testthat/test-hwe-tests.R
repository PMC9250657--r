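test_that("recursive test behaves across scales and degenerate input", {
  t_cnt <- recursive_ahwe_test(worked_counts)
  t_frq <- recursive_ahwe_test(worked_counts, scale = "frequencies")
  expect_equal(t_cnt$statistic, 120 * t_frq$statistic, tolerance = 1e-12)
  expect_identical(t_cnt$df, 6)
  ## doubling every count doubles the N-scaled statistic
  t_dbl <- recursive_ahwe_test(2 * worked_counts)
  expect_equal(t_dbl$statistic, 2 * t_cnt$statistic, tolerance = 1e-9)
  ## monomorphic sample is its own fixed point
  expect_equal(recursive_ahwe_test(c(40, 0, 0, 0, 0, 0, 0))$statistic, 0)
})

test_that("gamete-based test is exact under its own model", {
  G <- c(0.25, 0.3, 0.25, 0.2)
  counts <- 600 * zygote_freqs_from_gametes(G)
  t <- gamete_based_ahwe_test(counts, seed = 1)
  expect_lt(t$statistic, 1e-8)
  expect_equal(gamete_based_ahwe_test(c(55, 0, 0, 0, 0, 0, 0))$statistic, 0)
  expect_identical(t$df, 5)
})

test_that("double-reduction test (fitted mode) is exact under the alpha=0 model", {
  Pstar <- c(0.1, 0.05, 0.2, 0.25, 0.13, 0.1, 0.17)
  counts <- 300 * reduced_zygote_freqs_alpha0(Pstar)
  t <- double_reduction_test(counts, expected_mode = "fitted", seed = 2)
  expect_lt(t$statistic, 1e-6)
  cx <- c(25, 14, 18, 11, 9, 13, 30)
  t1 <- double_reduction_test(cx, expected_mode = "fitted", seed = 3)
  t2 <- double_reduction_test(2 * cx, expected_mode = "fitted", seed = 3)
  expect_equal(t2$statistic, 2 * t1$statistic, tolerance = 1e-4)
})

test_that("one-generation fitted expectations absorb double reduction entirely", {
  ## any alpha > 0 offspring distribution is exactly reproducible by some
  ## alpha = 0 parent, so the fitted-mode statistic stays at noise level
  ## even when the data carry strong double reduction
  Pstar <- c(0.1, 0.05, 0.2, 0.25, 0.13, 0.1, 0.17)
  counts <- 1000 * next_generation(Pstar, 0.25)
  t <- double_reduction_test(counts, expected_mode = "fitted", seed = 4)
  expect_lt(t$statistic, 1e-4)
})

test_that("equilibrium-mode double-reduction test is calibrated at its null", {
  ## data sampled at the alpha = 0 equilibrium: rejection near nominal
  equil <- dbinom(6:0, 6, 0.46)
  set.seed(401)
  rej <- 0L
  for (r in 1:120) {
    cx <- as.numeric(rmultinom(1, 100, equil))
    t <- double_reduction_test(cx, tol = 1e-8, max_iter = 4000,
                               n_restarts = 1)
    if (t$p_value < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / 120, 0.10)
  expect_gte(rej / 120, 0.0)
})

test_that("parental-equilibrium LR statistic is non-negative and nested", {
  set.seed(402)
  for (i in 1:4) {
    cx <- as.numeric(rmultinom(1, 120, r_genotype()))
    t <- parental_ahwe_lr_test(cx, tol = 1e-7, max_iter = 400, n_restarts = 1)
    expect_gte(t$statistic, 0)
    expect_identical(t$df, 1)
    ## the free-parent alternative can never fit worse than the
    ## equilibrium-constrained null
    expect_gte(t$em$alternative$log_likelihood,
               t$em$null$log_likelihood - 1e-4)
  }
})

test_that("allele-based collapsed test reproduces the allele-model expectations", {
  t <- allele_based_ahwe_test_collapsed(snp4_freqs)
  expect_equal(round(t$expected[[1]], 4), 0.0712)
  expect_identical(t$df, 2)
  ## exact allele-model input fits perfectly when p is estimated by ML
  ## (the midpoint rule is a different estimator and does not recover p
  ## from allele-model data away from p = 1/2)
  p <- 0.7; q <- 0.3
  t0 <- allele_based_ahwe_test_collapsed(c(p^6, 1 - p^6 - q^6, q^6),
                                         p_mode = "mle")
  expect_lt(t0$statistic, 1e-6)
  ## monomorphic input is flagged, not an error
  tm <- allele_based_ahwe_test_collapsed(c(60, 0, 0))
  expect_match(tm$note, "monomorphic")
})

test_that("collapsed recursive test matches binomial stationarity and mirrors", {
  ## uniform heterozygote expansion conserves the midpoint allele
  ## frequency, so the collapse of a binomial population is a fixed point
  ## of expand-iterate-collapse at the symmetric frequency
  b <- dbinom(6:0, 6, 0.5)
  tb <- recursive_ahwe_test_collapsed(c(b[1], sum(b[2:6]), b[7]))
  expect_lt(tb$statistic, 1e-4)
  t1 <- recursive_ahwe_test_collapsed(snp4_freqs)
  t2 <- recursive_ahwe_test_collapsed(rev(snp4_freqs))
  expect_equal(rev(unname(t2$expected)), unname(t1$expected),
               tolerance = 1e-9)
})

test_that("collapsed double-reduction LR is non-negative and calibrated", {
  set.seed(403)
  nonsig <- 0L
  for (r in 1:20) {
    cx <- as.numeric(rmultinom(1, 150, dbinom(6:0, 6, 0.55)))
    col <- c(cx[1], sum(cx[2:6]), cx[7])
    t <- double_reduction_test_collapsed(col)
    expect_gte(t$statistic, 0)
    if (t$p_value >= 0.05) nonsig <- nonsig + 1L
  }
  ## data generated without double reduction: non-significant >= 90%
  expect_gte(nonsig / 20, 0.9)
  ## degenerate pattern flagged, not an error
  td <- double_reduction_test_collapsed(c(0, 150, 0))
  expect_true(is.na(td$statistic))
})

test_that("the published collapsed double-reduction examples reproduce qualitatively", {
  ## goodness-of-fit mode: SNP-5 fits the double-reduction model, the
  ## other markers do not
  expect_gt(double_reduction_test_collapsed(c(0.1539, 0.6593, 0.1868),
                                            mode = "gof")$p_value, 0.05)
  expect_lt(double_reduction_test_collapsed(c(0.6308, 0.3385, 0.0308),
                                            mode = "gof")$p_value, 1e-6)
  expect_lt(double_reduction_test_collapsed(c(0.0421, 0.3053, 0.6526),
                                            mode = "gof")$p_value, 1e-6)
})

test_that("all chi-square statistics are invariant under allele relabelling", {
  cx <- c(22, 15, 11, 17, 9, 13, 25)
  expect_equal(recursive_ahwe_test(rev(cx))$statistic,
               recursive_ahwe_test(cx)$statistic, tolerance = 1e-9)
  expect_equal(gamete_based_ahwe_test(rev(cx), seed = 7)$statistic,
               gamete_based_ahwe_test(cx, seed = 7)$statistic,
               tolerance = 1e-4)
  expect_equal(
    double_reduction_test(rev(cx), expected_mode = "fitted", seed = 7)$statistic,
    double_reduction_test(cx, expected_mode = "fitted", seed = 7)$statistic,
    tolerance = 1e-4)
  expect_equal(allele_based_ahwe_test_collapsed(rev(snp4_freqs))$statistic,
               allele_based_ahwe_test_collapsed(snp4_freqs)$statistic,
               tolerance = 1e-9)
})

test_that("test results print a readable summary", {
  out <- capture.output(print(recursive_ahwe_test(worked_counts)))
  expect_true(any(grepl("recursive aHWE test", out)))
  expect_true(any(grepl("df = 6", out)))
})
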