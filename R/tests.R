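## Chi-square sum over classes with the zero-expected rule: a class with
## zero expected frequency contributes 0 if its observed frequency is also
## zero, +Inf otherwise.
chisq_terms <- function(obs_f, exp_f) {
  stopifnot(length(obs_f) == length(exp_f))
  terms <- numeric(length(obs_f))
  pos <- exp_f > 0
  terms[pos] <- (obs_f[pos] - exp_f[pos])^2 / exp_f[pos]
  terms[!pos & obs_f > 0] <- Inf
  terms
}

new_hex_test <- function(statistic, df, p_value, observed, expected,
                         method, scale, n, note = NULL, em = NULL) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         observed = observed, expected = expected, method = method,
         scale = scale, n = n, note = note, em = em),
    class = "hex_test")
}

#' @export
print.hex_test <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat("  chi-square/LR = ", format(signif(x$statistic, 6)),
      ", df = ", x$df,
      ", p = ", format(signif(x$p_value, 4)),
      "  [", x$scale, " scale, n = ", format(x$n), "]\n", sep = "")
  tab <- rbind(observed = signif(x$observed, 4),
               expected = signif(x$expected, 4))
  print(tab)
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

finish_test <- function(obs_f, exp_f, n, scale, df, method,
                        note = NULL, em = NULL) {
  stat_f <- sum(chisq_terms(obs_f, exp_f))
  stat <- if (scale == "counts") n * stat_f else stat_f
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_hex_test(stat, df, p, obs_f, exp_f, method, scale, n, note, em)
}

#' Recursive test for asymptotic Hardy-Weinberg equilibrium
#'
#' Compares the observed genotype frequencies P(0) with the
#' near-equilibrium frequencies P(g) obtained by iterating the
#' random-mating recursion g = `generations` rounds from the observed
#' distribution, using the chi-square statistic
#' N * sum_j (P_j(0) - P_j(g))^2 / P_j(g) with df = 6 (`scale = "counts"`).
#' `scale = "frequencies"` drops the factor N, the form under which the
#' published per-marker statistics of this test are reproducible.
#'
#' @param counts observed genotype counts (7 classes, 6A..6a).
#' @param alpha double-reduction rate used in the recursion.
#' @param generations rounds of random mating to near-equilibrium.
#' @param scale `"counts"` (N-scaled, default) or `"frequencies"`.
#' @return a `hex_test`.
#' @examples
#' recursive_ahwe_test(c(29, 21, 17, 10, 10, 10, 23))
#' @export
recursive_ahwe_test <- function(counts, alpha = 0, generations = 8,
                                scale = c("counts", "frequencies")) {
  counts <- as_genotype_counts(counts)
  scale <- match.arg(scale)
  n <- sum(counts)
  obs <- counts / n
  expd <- trajectory_endpoint(iterate_generations(obs, alpha, generations))
  finish_test(obs, expd, n, scale, df = 6, method = "recursive aHWE test")
}

#' Gamete-based test for asymptotic Hardy-Weinberg equilibrium
#'
#' Fits the four gamete frequencies by EM under the gamete-product
#' (equilibrium) model and tests the observed genotype frequencies against
#' the expected ones. With `expected_mode = "fitted"` the expected
#' frequencies are the fitted gamete products themselves (the direct
#' goodness-of-fit reading); with `"equilibrium"` the fit is carried
#' forward `generations` rounds of random mating, which is the
#' construction under which the published worked-example statistic is
#' reproducible.
#'
#' The degrees of freedom for this statistic lie between 7 - 1 - 1 = 5 and
#' 7 - 1 = 6; `df` defaults to 5.
#'
#' @inheritParams recursive_ahwe_test
#' @param df degrees of freedom (5 or 6).
#' @param expected_mode `"fitted"` or `"equilibrium"`.
#' @param tol,max_iter,n_restarts,seed EM settings, see
#'   [em_gamete_frequencies()].
#' @return a `hex_test`; the EM fit is attached as `$em`.
#' @export
gamete_based_ahwe_test <- function(counts, df = 5,
                                   expected_mode = c("fitted", "equilibrium"),
                                   generations = 8,
                                   scale = c("counts", "frequencies"),
                                   tol = 1e-9, max_iter = 10000,
                                   n_restarts = 3, seed = NULL) {
  counts <- as_genotype_counts(counts)
  scale <- match.arg(scale)
  expected_mode <- match.arg(expected_mode)
  n <- sum(counts)
  obs <- counts / n
  em <- em_gamete_frequencies(counts, tol, max_iter, n_restarts, seed)
  expd <- em$fitted
  if (expected_mode == "equilibrium") {
    expd <- trajectory_endpoint(iterate_generations(expd, 0, generations))
  }
  finish_test(obs, expd, n, scale, df,
              method = paste0("gamete-based aHWE test (", expected_mode, ")"),
              em = em)
}

#' Chi-square test for the presence of double reduction
#'
#' Fits the parental genotype frequencies by EM under the
#' no-double-reduction transmission model and tests the observed offspring
#' frequencies against the expected ones, with df defaulting to 5 (one
#' effective parameter beyond the allele frequency is absorbed; the
#' theoretical value lies between 5 and 6).
#'
#' Two expected-frequency constructions are available. The default,
#' `expected_mode = "equilibrium"`, reads the expected distribution at
#' generation `generations` of the alpha = 0 recursion started from the
#' fitted parent — in effect the asymptotic equilibrium implied by the
#' fitted model. This is the construction whose operating characteristics
#' (false-positive rate near nominal, substantial power against alpha > 0)
#' match the published simulation study. `expected_mode = "fitted"` is the
#' literal one-generation expected R(P-hat); it is retained for
#' completeness but has asymptotically no power against double reduction,
#' because any gamete pool generated with alpha > 0 is exactly reproducible
#' by some alpha = 0 parental population (see the methods vignette).
#'
#' @inheritParams gamete_based_ahwe_test
#' @return a `hex_test` with the parental EM fit attached as `$em`.
#' @export
double_reduction_test <- function(counts, df = 5,
                                  expected_mode = c("equilibrium", "fitted"),
                                  generations = 8,
                                  scale = c("counts", "frequencies"),
                                  tol = 1e-9, max_iter = 10000,
                                  n_restarts = 3, seed = NULL) {
  counts <- as_genotype_counts(counts)
  scale <- match.arg(scale)
  expected_mode <- match.arg(expected_mode)
  n <- sum(counts)
  obs <- counts / n
  em <- em_parental_genotypes_alpha0(counts, tol, max_iter, n_restarts, seed)
  expd <- if (expected_mode == "fitted") {
    em$fitted
  } else {
    trajectory_endpoint(
      iterate_generations(em$estimates$parental_freq, 0, generations))
  }
  finish_test(obs, expd, n, scale, df,
              method = paste0("double-reduction test (", expected_mode, ")"),
              em = em)
}

#' Likelihood-ratio test of parental equilibrium (aHWE)
#'
#' Tests whether the parental population, one generation back from the
#' observed sample, was itself at asymptotic Hardy-Weinberg equilibrium.
#' The alternative (L1) leaves the parental genotype frequencies free under
#' the alpha = 0 transmission model ([em_parental_genotypes_alpha0()]); the
#' null (L0) constrains the parent to equilibrium gamete products while
#' estimating the double-reduction rate ([em_joint_gamete_alpha()]). The
#' statistic LR = -2 (log L0 - log L1), floored at 0, is referred to
#' chi-square with 1 degree of freedom.
#'
#' @inheritParams gamete_based_ahwe_test
#' @return a `hex_test`; `$em` holds both fits.
#' @export
parental_ahwe_lr_test <- function(counts, tol = 1e-9, max_iter = 10000,
                                  n_restarts = 3, seed = NULL) {
  counts <- as_genotype_counts(counts)
  n <- sum(counts)
  obs <- counts / n
  fit1 <- em_parental_genotypes_alpha0(counts, tol, max_iter, n_restarts, seed)
  fit0 <- em_joint_gamete_alpha(counts, tol, max_iter, n_restarts, seed)
  lr <- max(0, -2 * (fit0$log_likelihood - fit1$log_likelihood))
  p <- stats::pchisq(lr, 1, lower.tail = FALSE)
  new_hex_test(lr, 1, p, obs, fit0$fitted,
               "parental aHWE likelihood-ratio test", "counts", n,
               em = list(null = fit0, alternative = fit1))
}

## Collapse a 7-class vector to (6A, A_a, 6a).
collapse3 <- function(v) {
  out <- c(v[1], sum(v[2:6]), v[7])
  names(out) <- COLLAPSED_LABELS
  out
}

collapsed_obs <- function(collapsed, pseudo_n) {
  x <- as_collapsed_counts(collapsed)
  tot <- sum(x)
  if (is_frequency_triple(x)) list(f = x / tot, n = pseudo_n)
  else list(f = x / tot, n = tot)
}

#' Allele-based aHWE test for dosage-ambiguous markers
#'
#' For collapsed three-class data, assumes triploid gametes form by random
#' combination of three alleles, so the expected class frequencies are
#' (p^6, 1 - p^6 - q^6, q^6). The statistic is computed on the frequency
#' scale by default (the scale on which the published per-marker
#' chi-squares and their df = 2 p-values are reproducible); pass
#' `scale = "counts"` with a count triple (or `pseudo_n`) for the N-scaled
#' form.
#'
#' @param collapsed counts or frequencies (6A, A_a, 6a).
#' @param p_mode allele-frequency estimator, see
#'   [estimate_allele_freq_collapsed()].
#' @param scale `"frequencies"` (default) or `"counts"`.
#' @param pseudo_n sample size to attach when `collapsed` is a frequency
#'   triple.
#' @return a `hex_test`.
#' @examples
#' allele_based_ahwe_test_collapsed(c(0.4000, 0.4875, 0.1125))
#' @export
allele_based_ahwe_test_collapsed <- function(collapsed,
                                             p_mode = c("midpoint", "mle"),
                                             scale = c("frequencies", "counts"),
                                             pseudo_n = 100) {
  scale <- match.arg(scale)
  p_mode <- match.arg(p_mode)
  ob <- collapsed_obs(collapsed, pseudo_n)
  p <- estimate_allele_freq_collapsed(collapsed, p_mode)
  q <- 1 - p
  expd <- c(p^6, 1 - p^6 - q^6, q^6)
  names(expd) <- COLLAPSED_LABELS
  note <- NULL
  if (p <= 0 || p >= 1) note <- "monomorphic: degenerate expected frequencies"
  finish_test(ob$f, expd, ob$n, scale, df = 2,
              method = paste0("allele-based aHWE test (p by ", p_mode, ")"),
              note = note)
}

#' Recursive aHWE test for dosage-ambiguous markers
#'
#' Expands the heterozygote mass uniformly over the five heterozygous
#' dosage classes (which conserves the midpoint allele frequency), iterates
#' the alpha = 0 random-mating recursion `generations` rounds, collapses
#' the endpoint back to three classes and computes the chi-square on the
#' frequency scale with df = 2.
#'
#' @inheritParams allele_based_ahwe_test_collapsed
#' @param generations rounds of random mating.
#' @return a `hex_test`.
#' @export
recursive_ahwe_test_collapsed <- function(collapsed, generations = 8,
                                          scale = c("frequencies", "counts"),
                                          pseudo_n = 100) {
  scale <- match.arg(scale)
  ob <- collapsed_obs(collapsed, pseudo_n)
  init <- c(ob$f[1], rep(ob$f[2] / 5, 5), ob$f[3])
  endp <- trajectory_endpoint(iterate_generations(init, 0, generations))
  expd <- collapse3(endp)
  finish_test(ob$f, expd, ob$n, scale, df = 2,
              method = "recursive aHWE test (collapsed)")
}

#' Double-reduction test for dosage-ambiguous markers
#'
#' Models the parental population as the alpha = 0 equilibrium
#' binomial(6, p) and the observed three-class data as the collapse of one
#' round of random mating with double-reduction rate alpha.
#'
#' `mode = "lr"` (default) maximises the likelihood over (p, alpha) and
#' over p with alpha = 0, and refers LR = -2 (log L0 - log L1) to
#' chi-square with 1 degree of freedom. `mode = "gof"` instead reports the
#' frequency-scale chi-square of the observed classes against the fitted
#' (p, alpha) expectations with df = 2 — a goodness-of-fit reading of the
#' double-reduction model under which the published per-marker
#' chrysanthemum results are qualitatively reproducible (a *small*
#' statistic there means the double-reduction model fits).
#'
#' @inheritParams allele_based_ahwe_test_collapsed
#' @param mode `"lr"` or `"gof"`.
#' @return a `hex_test`; estimates are attached as `$em`.
#' @export
double_reduction_test_collapsed <- function(collapsed, pseudo_n = 100,
                                            mode = c("lr", "gof")) {
  mode <- match.arg(mode)
  ob <- collapsed_obs(collapsed, pseudo_n)
  x <- ob$f * ob$n
  if (ob$f[1] + ob$f[3] >= 1 - 1e-12 || ob$f[2] >= 1 - 1e-12) {
    ## no information about p and alpha jointly
    return(new_hex_test(NA_real_, 1, NA_real_, ob$f, rep(NA_real_, 3),
                        "double-reduction LR test (collapsed)", "counts",
                        ob$n, note = "degenerate class pattern"))
  }
  ll_fun <- function(p, a) {
    e <- collapse3(next_generation(stats::dbinom(6:0, 6, p), a))
    sum(x * safe_log(e))
  }
  ## null: alpha = 0 (binomial is stationary, expected = collapse of it)
  ll0_of_p <- function(p) ll_fun(p, 0)
  opt0 <- stats::optimize(ll0_of_p, c(1e-6, 1 - 1e-6), maximum = TRUE,
                          tol = 1e-10)
  ## alternative: free (p, alpha)
  neg <- function(th) -ll_fun(th[1], th[2])
  best1 <- NULL
  for (a0 in c(0.02, 0.1, 0.2)) {
    o <- stats::optim(c(opt0$maximum, a0), neg, method = "L-BFGS-B",
                      lower = c(1e-6, 0), upper = c(1 - 1e-6, ALPHA_MAX))
    if (is.null(best1) || o$value < best1$value) best1 <- o
  }
  lr <- max(0, -2 * (opt0$objective - (-best1$value)))
  p_hat <- best1$par[1]; a_hat <- best1$par[2]
  expd <- collapse3(next_generation(stats::dbinom(6:0, 6, p_hat), a_hat))
  est <- list(p = p_hat, alpha = a_hat, p_null = opt0$maximum,
              logL1 = -best1$value, logL0 = opt0$objective)
  if (mode == "gof") {
    return(finish_test(ob$f, expd, ob$n, "frequencies", df = 2,
                       method = "double-reduction model fit (collapsed, gof)",
                       em = est))
  }
  new_hex_test(lr, 1, stats::pchisq(lr, 1, lower.tail = FALSE),
               ob$f, expd, "double-reduction LR test (collapsed)",
               "counts", ob$n, em = est)
}
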