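#' Collapse seven-class genotype counts to three observable classes
#'
#' @param counts genotype counts (6A..6a).
#' @return collapsed counts (6A, A_a, 6a); totals are preserved.
#' @examples
#' collapse_counts(c(29, 21, 17, 10, 10, 10, 23))  # 29, 68, 23
#' @export
collapse_counts <- function(counts) {
  counts <- as_genotype_counts(counts)
  as_collapsed_counts(collapse3(counts))
}

#' Sample offspring genotype counts under one round of random mating
#'
#' Draws a multinomial sample of size `n` from the offspring distribution
#' `next_generation(parent, alpha)`.
#'
#' @param parent parental genotype distribution (6A..6a).
#' @param alpha double-reduction rate.
#' @param n sample size (>= 1).
#' @param seed optional integer seed; the global RNG state is restored.
#' @return genotype counts (length 7) summing to `n`.
#' @export
sample_offspring_counts <- function(parent, alpha = 0, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  off <- next_generation(parent, alpha)
  counts <- with_local_seed(seed, function() {
    as.numeric(stats::rmultinom(1, n, off))
  })
  names(counts) <- GENOTYPE_LABELS
  counts
}

#' Monte-Carlo study configuration
#'
#' @param truth truth specification: a 7-class parental genotype
#'   distribution (`truth_type = "genotype"`) or a 4-class gamete
#'   distribution whose equilibrium products form the parent
#'   (`truth_type = "gamete"`).
#' @param truth_type `"genotype"` or `"gamete"`.
#' @param alpha double-reduction rate(s) used to generate offspring.
#' @param n_list offspring sample sizes.
#' @param replicates Monte-Carlo replicates per cell.
#' @param level nominal test level.
#' @param seed integer master seed; per-cell substream seeds are derived
#'   from it deterministically.
#' @param test which test to apply in [run_power_study()]: one of
#'   `"double_reduction"`, `"parental_lr"`, `"recursive"`, `"gamete"`.
#' @param test_args extra arguments passed to the test function.
#' @param em_args EM settings used inside tests/estimators (a list; e.g.
#'   `list(tol = 1e-8, n_restarts = 1)`).
#' @param offspring_at sampled distribution: `"next_generation"` (one round
#'   of random mating separates the parental truth from the sampled
#'   offspring, default) or `"equilibrium"` (offspring sampled at the
#'   asymptotic equilibrium reached from the truth after
#'   `equilibrium_generations` rounds at the cell's alpha).
#' @param equilibrium_generations rounds used by
#'   `offspring_at = "equilibrium"`.
#' @return a `hex_sim_config` list.
#' @export
simulation_config <- function(truth, truth_type = c("genotype", "gamete"),
                              alpha = 0, n_list = c(100, 200, 400),
                              replicates = 1000, level = 0.05, seed = 1,
                              test = c("double_reduction", "parental_lr",
                                       "recursive", "gamete"),
                              test_args = list(), em_args = list(),
                              offspring_at = c("next_generation",
                                               "equilibrium"),
                              equilibrium_generations = 8) {
  truth_type <- match.arg(truth_type)
  test <- match.arg(test)
  offspring_at <- match.arg(offspring_at)
  parent <- if (truth_type == "gamete") {
    zygote_freqs_from_gametes(truth)
  } else {
    as_genotype_distribution(truth)
  }
  if (replicates < 1) stop("replicates must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  structure(
    list(parent = parent, truth_type = truth_type,
         alpha = vapply(alpha, check_alpha, numeric(1)),
         n_list = as.integer(n_list), replicates = as.integer(replicates),
         level = level, seed = as.integer(seed), test = test,
         test_args = test_args, em_args = em_args,
         offspring_at = offspring_at,
         equilibrium_generations = equilibrium_generations),
    class = "hex_sim_config")
}

## Distribution the replicates are drawn from, per the configured design.
sampled_distribution <- function(config, alpha) {
  if (config$offspring_at == "equilibrium") {
    trajectory_endpoint(iterate_generations(config$parent, alpha,
                                            config$equilibrium_generations))
  } else {
    next_generation(config$parent, alpha)
  }
}

## Deterministic per-cell substream seed, kept within 32-bit integer range.
cell_seed <- function(seed, cell) {
  (as.numeric(seed) * 7919 + cell * 104729) %% 2147483647
}

apply_test <- function(test, counts, em_args, test_args) {
  args <- c(list(counts), test_args, em_args)
  switch(test,
         double_reduction = do.call(double_reduction_test, args),
         parental_lr = do.call(parental_ahwe_lr_test, args),
         recursive = do.call(recursive_ahwe_test,
                             c(list(counts), test_args)),
         gamete = do.call(gamete_based_ahwe_test, args))
}

#' Monte-Carlo power / false-positive-rate study
#'
#' For each (alpha, N) cell, simulates `replicates` offspring samples from
#' the configured parental truth, applies the configured test at the
#' nominal level, and records the rejection proportion. EM failures in a
#' replicate are counted and reported, not fatal.
#'
#' @param config a [simulation_config()].
#' @return a `hex_study` data.frame with one row per cell: `alpha`, `n`,
#'   `replicates`, `rejections`, `rejection_rate`, `failures`.
#' @export
run_power_study <- function(config) {
  stopifnot(inherits(config, "hex_sim_config"))
  cells <- expand.grid(alpha = config$alpha, n = config$n_list,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- cells$alpha[i]; n <- cells$n[i]
    off <- sampled_distribution(config, a)
    res <- with_local_seed(cell_seed(config$seed, i), function() {
      rej <- 0L; fail <- 0L
      for (r in seq_len(config$replicates)) {
        counts <- as.numeric(stats::rmultinom(1, n, off))
        tst <- tryCatch(
          apply_test(config$test, counts, config$em_args, config$test_args),
          error = function(e) NULL)
        if (is.null(tst) || is.na(tst$p_value)) fail <- fail + 1L
        else if (tst$p_value < config$level) rej <- rej + 1L
      }
      c(rej = rej, fail = fail)
    })
    rows[[i]] <- data.frame(
      alpha = a, n = n, replicates = config$replicates,
      rejections = res[["rej"]],
      rejection_rate = res[["rej"]] / config$replicates,
      failures = res[["fail"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "test") <- config$test
  attr(out, "level") <- config$level
  attr(out, "seed") <- config$seed
  class(out) <- c("hex_study", "data.frame")
  out
}

#' Monte-Carlo study of the joint gamete/alpha estimator
#'
#' For each (alpha, N) cell, simulates offspring samples, runs the joint
#' EM ([em_joint_gamete_alpha()]), and tabulates the mean and standard
#' deviation of each gamete-frequency estimate and of alpha-hat.
#'
#' @param config a [simulation_config()]; the `test` field is ignored.
#' @return a `hex_study` data.frame with one row per cell carrying
#'   `mean_*` and `sd_*` columns for `AAA`, `AAa`, `Aaa`, `aaa`, `alpha`.
#' @export
run_estimator_study <- function(config) {
  stopifnot(inherits(config, "hex_sim_config"))
  cells <- expand.grid(alpha = config$alpha, n = config$n_list,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- cells$alpha[i]; n <- cells$n[i]
    off <- sampled_distribution(config, a)
    est <- with_local_seed(cell_seed(config$seed, i), function() {
      out <- matrix(NA_real_, config$replicates, 5L)
      for (r in seq_len(config$replicates)) {
        counts <- as.numeric(stats::rmultinom(1, n, off))
        fit <- tryCatch(
          do.call(em_joint_gamete_alpha, c(list(counts), config$em_args)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          out[r, ] <- c(fit$estimates$gamete_freq, fit$estimates$alpha)
        }
      }
      out
    })
    mu <- colMeans(est, na.rm = TRUE)
    sdv <- apply(est, 2, stats::sd, na.rm = TRUE)
    row <- data.frame(alpha = a, n = n, replicates = config$replicates,
                      failures = sum(is.na(est[, 5])))
    nm <- c(GAMETE_LABELS, "alpha")
    for (k in 1:5) {
      row[[paste0("mean_", nm[k])]] <- mu[k]
      row[[paste0("sd_", nm[k])]] <- sdv[k]
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- config$seed
  class(out) <- c("hex_study", "data.frame")
  out
}
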