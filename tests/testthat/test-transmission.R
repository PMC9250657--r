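test_that("single-parent gamete frequencies match the segregation model", {
  ## homozygotes transmit their own gamete only
  expect_equal(unname(gamete_distribution(6, 0.2)), c(1, 0, 0, 0))
  expect_equal(unname(gamete_distribution(0, 0.2)), c(0, 0, 0, 1))
  ## balanced heterozygote without double reduction
  expect_equal(unname(gamete_distribution(3, 0)),
               c(1/20, 9/20, 9/20, 1/20))
  ## 5A1a at the chromatid-segregation bound
  expect_equal(unname(gamete_distribution(5, 3/11)),
               c(1/2 + 1/22, 1/2 - 1/11, 1/22, 0))
  expect_error(gamete_distribution(7, 0), "0..6")
  expect_error(gamete_distribution(3, 0.4), "3/11")
})

test_that("every transmission row sums to 1 and conserves half-dosage", {
  set.seed(101)
  for (alpha in c(0, 3/11, runif(48, 0, 3/11))) {
    m <- gamete_transition_matrix(alpha)
    expect_equal(unname(rowSums(m)), rep(1, 7))
    ## mean gamete dosage from a parent of dosage d is exactly d/2
    expect_equal(unname(as.numeric(m %*% (3:0))), (6:0) / 2)
  }
})

test_that("gamete pooling mixes rows and conserves allele frequency", {
  expect_equal(unname(pool_gametes(c(1, 0, 0, 0, 0, 0, 0), 0.1)),
               c(1, 0, 0, 0))
  expect_equal(unname(pool_gametes(c(0.5, 0, 0, 0, 0, 0, 0.5), 0.23)),
               c(0.5, 0, 0, 0.5))
  set.seed(102)
  for (i in 1:20) {
    pop <- r_genotype()
    alpha <- runif(1, 0, 3/11)
    g <- pool_gametes(pop, alpha)
    expect_equal(sum((3:0) * g), mean_dosage(pop) / 2, tolerance = 1e-12)
  }
})

test_that("random-mating step equals the mating-type summation oracle", {
  set.seed(103)
  for (i in 1:25) {
    pop <- r_genotype()
    alpha <- runif(1, 0, 3/11)
    expect_equal(unname(next_generation(pop, alpha)),
                 mating_type_offspring(pop, alpha), tolerance = 1e-12)
  }
  ## published transmission-table cell: a 5A1a x 5A1a mating contributes
  ## (1/2 + alpha/6)^2 = 1/4 + alpha/6 + alpha^2/36 to offspring 6A
  for (alpha in c(0, 0.1, 3/11)) {
    g5 <- gamete_distribution(5, alpha)
    expect_equal(g5[[1]]^2, 1/4 + alpha/6 + alpha^2/36, tolerance = 1e-14)
  }
})

test_that("monomorphic populations are fixed points", {
  mono <- c(1, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(next_generation(mono, 0.2)), mono)
  traj <- iterate_generations(mono, 0.1, 10)
  expect_equal(nrow(traj), 11L)
  for (r in seq_len(nrow(traj))) {
    expect_equal(as.numeric(traj[r, -1]), mono)
  }
})

test_that("allele frequency is conserved along any trajectory", {
  set.seed(104)
  for (i in 1:10) {
    init <- r_genotype()
    alpha <- runif(1, 0, 3/11)
    traj <- iterate_generations(init, alpha, 30)
    p0 <- allele_frequency(init)
    for (r in seq_len(nrow(traj))) {
      expect_equal(allele_frequency(as.numeric(traj[r, -1])), p0,
                   tolerance = 1e-12)
    }
  }
})

test_that("binomial dosage distributions are stationary without double reduction", {
  for (p in c(0.05, 0.3, 0.5, 0.82)) {
    b <- dbinom(6:0, 6, p)
    expect_equal(unname(next_generation(b, 0)), b, tolerance = 1e-14)
  }
})

test_that("trajectories stabilise by 8-9 rounds and equilibria depend on alpha", {
  init <- c(0.1, 0.05, 0.2, 0.25, 0.13, 0.1, 0.17)
  traj <- iterate_generations(init, 0, 9)
  d89 <- max(abs(as.numeric(traj[10, -1]) - as.numeric(traj[9, -1])))
  expect_lt(d89, 1e-3)
  ## limit at alpha = 0 is the binomial with the conserved allele frequency
  eq <- equilibrium_distribution(init, 0, tol = 1e-10)
  expect_true(eq$converged)
  expect_equal(unname(eq$distribution),
               dbinom(6:0, 6, allele_frequency(init)), tolerance = 1e-6)
  ## already-stationary input converges immediately
  eq0 <- equilibrium_distribution(c(1, 0, 0, 0, 0, 0, 0), 0.2)
  expect_identical(eq0$generations_used, 0L)
  ## double reduction shifts the equilibrium itself
  eq_a <- equilibrium_distribution(init, 3/11, tol = 1e-10)
  expect_gt(max(abs(eq_a$distribution - eq$distribution)), 1e-3)
})

test_that("gamete products reproduce the hand-computed zygote frequencies", {
  expect_equal(unname(zygote_freqs_from_gametes(c(1, 0, 0, 0))),
               c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(zygote_freqs_from_gametes(c(0.3, 0.2, 0.35, 0.15))),
               c(0.09, 0.12, 0.25, 0.23, 0.1825, 0.105, 0.0225),
               tolerance = 1e-12)
  set.seed(105)
  for (i in 1:10) {
    g <- r_gamete()
    expect_equal(swap_alleles(zygote_freqs_from_gametes(g)),
                 unname(zygote_freqs_from_gametes(swap_alleles(g))),
                 tolerance = 1e-12)
  }
})

test_that("closed-form alpha=0 offspring frequencies match the convolution", {
  ## parent all 3A3a: offspring 6A frequency is (1/20)^2
  p3 <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(reduced_zygote_freqs_alpha0(p3)[[1]], 1/400)
  expect_equal(reduced_zygote_freqs_alpha0(c(0, 0, 0, 0, 0, 0, 1))[[7]], 1)
  set.seed(106)
  for (i in 1:20) {
    pop <- r_genotype()
    expect_equal(unname(reduced_zygote_freqs_alpha0(pop)),
                 unname(next_generation(pop, 0)), tolerance = 1e-12)
  }
})

test_that("allele relabelling commutes with the transmission operations", {
  set.seed(107)
  for (i in 1:10) {
    pop <- r_genotype()
    alpha <- runif(1, 0, 3/11)
    expect_equal(rev(unname(pool_gametes(swap_alleles(pop), alpha))),
                 unname(pool_gametes(pop, alpha)), tolerance = 1e-12)
    expect_equal(swap_alleles(next_generation(swap_alleles(pop), alpha)),
                 unname(next_generation(pop, alpha)), tolerance = 1e-12)
  }
})

test_that("trajectory export writes a readable 12-digit TSV", {
  traj <- iterate_generations(c(0.1, 0.05, 0.2, 0.25, 0.13, 0.1, 0.17), 0, 12)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(traj, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 13L)
  expect_equal(names(back)[1], "generation")
  expect_equal(back$f_6A, signif(traj$f_6A, 12))
})

test_that("distribution validators reject malformed input", {
  expect_error(as_genotype_distribution(rep(0.2, 5)), "7 classes")
  expect_error(as_genotype_distribution(c(0.5, 0.6, 0, 0, 0, 0, 0)), "sum to 1")
  expect_error(as_gamete_distribution(c(-0.1, 0.5, 0.3, 0.3)), "non-negative")
  expect_error(iterate_generations(r_genotype(), 0, -1), "non-negative")
})
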