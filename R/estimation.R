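## Index helper for the gamete-pair convolution: ordered gamete pair (i, j)
## (i, j in 1..4 over gamete dosage 3..0) lands in zygote class i + j - 1.
PAIR_CLASS_INDEX <- outer(1:4, 1:4, "+") - 1L

## Expected per-slot gamete usage given class weights w (length 7):
## e_i = 2 G_i sum_j G_j w[i + j - 1].
expected_gamete_usage <- function(G, w) {
  W <- matrix(w[PAIR_CLASS_INDEX], 4L, 4L)
  2 * G * as.numeric(W %*% G)
}

## Run fn with a locally seeded RNG, restoring global state afterwards.
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

random_simplex <- function(k) {
  x <- stats::rgamma(k, 1)
  x / sum(x)
}

safe_log <- function(x) log(pmax(x, 1e-300))

new_em_result <- function(method, estimates, fitted, log_likelihood,
                          iterations, converged, n_restarts_used,
                          boundary = FALSE) {
  structure(
    list(method = method, estimates = estimates, fitted = fitted,
         log_likelihood = log_likelihood, iterations = iterations,
         converged = converged, n_restarts_used = n_restarts_used,
         boundary = boundary),
    class = "hex_em")
}

#' @export
print.hex_em <- function(x, ...) {
  cat("EM fit (", x$method, ")\n", sep = "")
  for (nm in names(x$estimates)) {
    v <- x$estimates[[nm]]
    cat("  ", nm, ": ", paste(signif(v, 5), collapse = " "), "\n", sep = "")
  }
  cat("  logLik ", format(x$log_likelihood), " after ", x$iterations,
      " iterations (converged: ", x$converged, ", restarts: ",
      x$n_restarts_used, ")\n", sep = "")
  invisible(x)
}

#' EM estimation of gamete frequencies under equilibrium
#'
#' Maximises the multinomial log-likelihood sum_j N_j log Q_j, where the
#' expected genotype frequencies Q_j are the gamete-product (HWE)
#' frequencies of [zygote_freqs_from_gametes()]. The heterozygote classes
#' 4A2a, 3A3a and 2A4a each arise from two distinct gamete pairings; the
#' E-step splits their counts over the pairings by posterior weight and the
#' M-step sets each gamete frequency to its expected usage over the 2N
#' gamete slots.
#'
#' One moment-based start (binomial gamete frequencies at the observed
#' allele frequency) is always used; additional restarts draw random
#' starting points from the simplex, and the best final likelihood wins.
#'
#' @param counts observed genotype counts (7 classes, 6A..6a).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap per restart.
#' @param n_restarts total number of starts (>= 1).
#' @param seed optional integer seed for the random restarts.
#' @return a `hex_em` object; `estimates$gamete_freq` holds the MLE,
#'   `fitted` the implied genotype frequencies.
#' @export
em_gamete_frequencies <- function(counts, tol = 1e-9, max_iter = 10000,
                                  n_restarts = 3, seed = NULL) {
  counts <- as_genotype_counts(counts)
  N <- sum(counts)
  p <- sum(GENOTYPE_DOSAGE * counts) / N / 6
  starts <- list(stats::dbinom(3:0, 3, p))
  extra <- with_local_seed(seed, function() {
    lapply(seq_len(max(0, n_restarts - 1)), function(i) random_simplex(4))
  })
  starts <- c(starts, extra)

  run <- function(G) {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Q <- gamete_self_convolution(G)
      ll <- sum(counts * safe_log(Q))
      if (ll < ll_old - 1e-8) {
        warning("EM log-likelihood decreased; numerical trouble")
      }
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      e <- expected_gamete_usage(G, counts / pmax(Q, 1e-300))
      G <- e / (2 * N)
    }
    list(G = G, ll = ll, it = it, converged = converged)
  }

  best <- NULL
  for (s in starts) {
    r <- run(s)
    if (is.null(best) || r$ll > best$ll) best <- r
  }
  G <- as_gamete_distribution(best$G)
  new_em_result("gamete_frequencies",
                list(gamete_freq = G),
                zygote_freqs_from_gametes(G),
                best$ll, best$it, best$converged, length(starts))
}

#' EM estimation of parental genotype frequencies without double reduction
#'
#' Treats the observed genotypes as offspring of one round of random mating
#' at alpha = 0 and maximises sum_j N_j log R_j(P) over the parental
#' genotype distribution P, where R(P) is the offspring distribution of
#' [reduced_zygote_freqs_alpha0()]. The latent variables are the ordered
#' transmitted-gamete pair of each offspring and the parental genotype each
#' gamete came from; the M-step sets each parental frequency to its
#' expected share of the 2N parental slots.
#'
#' The offspring distribution depends on P only through its gamete pool, so
#' the parental MLE is not unique: the fitted offspring frequencies
#' (`fitted`) are the identified quantity, and `estimates$parental_freq`
#' reports the representative the EM converged to.
#'
#' @inheritParams em_gamete_frequencies
#' @return a `hex_em` object with `estimates$parental_freq` and `fitted`
#'   (expected offspring frequencies).
#' @export
em_parental_genotypes_alpha0 <- function(counts, tol = 1e-9,
                                         max_iter = 10000, n_restarts = 3,
                                         seed = NULL) {
  counts <- as_genotype_counts(counts)
  N <- sum(counts)
  M <- gamete_transition_matrix(0)
  starts <- list(as.numeric(counts) / N)
  extra <- with_local_seed(seed, function() {
    lapply(seq_len(max(0, n_restarts - 1)), function(i) random_simplex(7))
  })
  starts <- c(starts, extra)

  run <- function(P) {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Gp <- as.numeric(crossprod(M, P))
      R <- gamete_self_convolution(Gp)
      ll <- sum(counts * safe_log(R))
      if (ll < ll_old - 1e-8) {
        warning("EM log-likelihood decreased; numerical trouble")
      }
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      e <- expected_gamete_usage(Gp, counts / pmax(R, 1e-300))
      ## attribute pooled gametes back to parental genotypes
      u <- as.numeric(M %*% (e / pmax(Gp, 1e-300))) * P
      P <- u / (2 * N)
    }
    list(P = P, ll = ll, it = it, converged = converged)
  }

  best <- NULL
  for (s in starts) {
    r <- run(s)
    if (is.null(best) || r$ll > best$ll) best <- r
  }
  P <- as_genotype_distribution(best$P)
  fitted <- next_generation(P, 0)
  new_em_result("parental_genotypes_alpha0",
                list(parental_freq = P),
                fitted, best$ll, best$it, best$converged, length(starts))
}

#' Joint EM estimation of parental gamete frequencies and double reduction
#'
#' Assumes the parental population is itself at equilibrium — its genotype
#' frequencies are the gamete products of a generation-(t-1) gamete
#' distribution G — and that the observed genotypes arose from one round of
#' random mating with double-reduction rate alpha. The offspring class
#' probabilities are `next_generation(zygote_freqs_from_gametes(G), alpha)`
#' and the multinomial log-likelihood is maximised over (G, alpha) with
#' alpha in [0, 3/11].
#'
#' The E-step tracks, for each offspring, the transmitted gamete pair, the
#' parental genotype behind each transmitted gamete, and the
#' generation-(t-1) gamete pair that formed that parent. The M-step updates
#' G from the expected usage of the 4N founding gamete slots and updates
#' alpha by one-dimensional bounded maximisation of the expected
#' complete-data log-likelihood (a concave sum of logs of linear functions
#' of alpha).
#'
#' Because alpha and the gamete frequencies trade off, plain EM can crawl
#' near the ridge of the likelihood; after the EM phase the solution is
#' polished by bounded quasi-Newton (L-BFGS-B) started from the EM point
#' (`polish = TRUE`, default). The reported log-likelihood is the best of
#' the two phases.
#'
#' @inheritParams em_gamete_frequencies
#' @param alpha_init starting value for alpha (interior of the bound).
#' @param polish run a quasi-Newton refinement after EM.
#' @return a `hex_em` object with `estimates$gamete_freq`,
#'   `estimates$alpha`, `estimates$parental_freq` (the implied equilibrium
#'   parent), and `fitted` offspring frequencies. `boundary` flags an alpha
#'   estimate within 1e-4 of either end of [0, 3/11].
#' @export
em_joint_gamete_alpha <- function(counts, tol = 1e-9, max_iter = 10000,
                                  n_restarts = 3, seed = NULL,
                                  alpha_init = 0.05, polish = TRUE) {
  counts <- as_genotype_counts(counts)
  N <- sum(counts)
  p <- sum(GENOTYPE_DOSAGE * counts) / N / 6
  starts <- list(list(G = stats::dbinom(3:0, 3, p), a = alpha_init))
  extra <- with_local_seed(seed, function() {
    lapply(seq_len(max(0, n_restarts - 1)), function(i) {
      list(G = random_simplex(4), a = stats::runif(1, 0.01, ALPHA_MAX - 0.01))
    })
  })
  starts <- c(starts, extra)

  run <- function(G, a) {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Q <- gamete_self_convolution(G)
      M <- TRANSITION_CONST + a * TRANSITION_SLOPE
      Gp <- as.numeric(crossprod(M, Q))
      O <- gamete_self_convolution(Gp)
      ll <- sum(counts * safe_log(O))
      if (ll < ll_old - 1e-8) {
        warning("EM log-likelihood decreased; numerical trouble")
      }
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      ## transmitted-gamete usage over the 2N offspring slots
      e <- expected_gamete_usage(Gp, counts / pmax(O, 1e-300))
      ## parental genotype behind each transmitted gamete
      C <- Q * sweep(M, 2L, e / pmax(Gp, 1e-300), "*")   # 7 x 4
      v <- rowSums(C)
      ## founding gamete pair behind each parent
      f <- expected_gamete_usage(G, v / pmax(Q, 1e-300))
      G <- f / (4 * N)
      ## bounded M-step for alpha on the expected complete-data loglik,
      ## a concave sum of logs of functions affine in alpha
      keep <- C > 1e-12
      if (any(keep)) {
        ck <- C[keep]
        ak <- TRANSITION_CONST[keep]
        bk <- TRANSITION_SLOPE[keep]
        obj <- function(x) sum(ck * log(pmax(ak + bk * x, 1e-300)))
        a <- stats::optimize(obj, c(0, ALPHA_MAX), maximum = TRUE,
                             tol = 1e-8)$maximum
      }
    }
    list(G = G, a = a, ll = ll, it = it, converged = converged)
  }

  ## observed-data log-likelihood as a function of (G, alpha)
  joint_ll <- function(G, a) {
    Q <- gamete_self_convolution(G)
    Gp <- as.numeric(crossprod(TRANSITION_CONST + a * TRANSITION_SLOPE, Q))
    sum(counts * safe_log(gamete_self_convolution(Gp)))
  }
  refine <- function(r) {
    th0 <- c(log(pmax(r$G[1:3], 1e-12) / pmax(r$G[4], 1e-12)),
             min(max(r$a, 1e-9), ALPHA_MAX - 1e-9))
    nll <- function(th) {
      z <- exp(pmin(c(th[1:3], 0), 500))
      -joint_ll(z / sum(z), th[4])
    }
    o <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B",
                   lower = c(-30, -30, -30, 0),
                   upper = c(30, 30, 30, ALPHA_MAX),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(o) || -o$value <= r$ll) return(r)
    z <- exp(pmin(c(o$par[1:3], 0), 500))
    list(G = z / sum(z), a = o$par[4], ll = -o$value, it = r$it,
         converged = TRUE)
  }

  best <- NULL
  for (s in starts) {
    r <- run(s$G, s$a)
    if (polish) r <- refine(r)
    if (is.null(best) || r$ll > best$ll) best <- r
  }
  G <- as_gamete_distribution(best$G)
  a <- min(max(best$a, 0), ALPHA_MAX)
  parent <- zygote_freqs_from_gametes(G)
  new_em_result("joint_gamete_alpha",
                list(gamete_freq = G, alpha = a, parental_freq = parent),
                next_generation(parent, a),
                best$ll, best$it, best$converged, length(starts),
                boundary = (a < 1e-4 || a > ALPHA_MAX - 1e-4))
}

#' Allele frequency from collapsed three-class data
#'
#' For dosage-ambiguous markers only the classes 6A, any-heterozygote and
#' 6a are observed. Two estimators of the A-allele frequency are provided:
#' `midpoint` assigns the heterozygote class its mean dosage 3 (half its
#' mass to each allele), giving p = f(6A) + f(A_a)/2; `mle` maximises the
#' multinomial likelihood against the allele-model class expectations
#' (p^6, 1 - p^6 - q^6, q^6).
#'
#' @param collapsed counts or frequencies for (6A, A_a, 6a).
#' @param mode `"midpoint"` (default) or `"mle"`.
#' @return allele frequency p of A.
#' @export
estimate_allele_freq_collapsed <- function(collapsed,
                                           mode = c("midpoint", "mle")) {
  x <- as_collapsed_counts(collapsed)
  mode <- match.arg(mode)
  f <- x / sum(x)
  if (mode == "midpoint") return(unname(f[1] + f[2] / 2))
  nll <- function(p) {
    q <- 1 - p
    e <- c(p^6, 1 - p^6 - q^6, q^6)
    -sum(x * safe_log(e))
  }
  stats::optimize(nll, c(1e-9, 1 - 1e-9))$minimum
}
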