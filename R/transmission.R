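#' Gamete transition matrix for a given double-reduction rate
#'
#' Row d (ordered 6A..6a) gives the frequencies of the four triploid gametes
#' (AAA, AAa, Aaa, aaa) produced by a parent carrying d copies of A. Without
#' double reduction (alpha = 0) the rows are the hypergeometric draws of 3
#' chromosomes out of 6; double reduction moves mass towards the
#' parent-homozygous gametes. Every row sums to 1 identically in alpha and
#' has mean gamete dosage d/2.
#'
#' @param alpha double-reduction rate in [0, 3/11].
#' @return 7 x 4 matrix, rows 6A..6a, columns AAA..aaa.
#' @export
gamete_transition_matrix <- function(alpha) {
  alpha <- check_alpha(alpha)
  m <- TRANSITION_CONST + alpha * TRANSITION_SLOPE
  dimnames(m) <- list(GENOTYPE_LABELS, GAMETE_LABELS)
  m
}

## The transition matrix is affine in alpha: M(alpha) = CONST + alpha * SLOPE.
TRANSITION_CONST <- rbind(
  c(1, 0, 0, 0),
  c(1/2, 1/2, 0, 0),
  c(1/5, 3/5, 1/5, 0),
  c(1/20, 9/20, 9/20, 1/20),
  c(0, 1/5, 3/5, 1/5),
  c(0, 0, 1/2, 1/2),
  c(0, 0, 0, 1))
TRANSITION_SLOPE <- rbind(
  c(0, 0, 0, 0),
  c(1/6, -1/3, 1/6, 0),
  c(1/5, -1/3, 1/15, 1/15),
  c(3/20, -3/20, -3/20, 3/20),
  c(1/15, 1/15, -1/3, 1/5),
  c(0, 1/6, -1/3, 1/6),
  c(0, 0, 0, 0))

#' Gamete frequencies from one parental genotype
#'
#' @param dosage parental A-dosage, integer 0..6.
#' @param alpha double-reduction rate in [0, 3/11].
#' @return gamete distribution (AAA, AAa, Aaa, aaa).
#' @examples
#' gamete_distribution(3, 0)          # (1/20, 9/20, 9/20, 1/20)
#' gamete_distribution(5, 3/11)
#' @export
gamete_distribution <- function(dosage, alpha = 0) {
  if (!is.numeric(dosage) || length(dosage) != 1L || is.na(dosage) ||
      dosage != round(dosage) || dosage < 0 || dosage > 6) {
    stop("dosage must be an integer in 0..6")
  }
  m <- gamete_transition_matrix(alpha)
  as_gamete_distribution(m[7L - dosage, ])
}

#' Population gamete pool
#'
#' The gamete pool of a panmictic population is the mixture of each
#' genotype's gamete output weighted by its frequency. The pooled mean
#' gamete dosage is exactly half the population mean parental dosage, so
#' the allele frequency is conserved across a round of random mating.
#'
#' @param pop genotype distribution (6A..6a).
#' @param alpha double-reduction rate.
#' @return gamete distribution.
#' @export
pool_gametes <- function(pop, alpha = 0) {
  pop <- as_genotype_distribution(pop)
  m <- gamete_transition_matrix(alpha)
  as_gamete_distribution(as.numeric(crossprod(m, pop)))
}

## Self-convolution of a gamete distribution: random union of two gametes.
## G is indexed 1..4 over gamete dosage 3..0; offspring class index
## k = i + j - 1 runs 1..7 over zygote dosage 6..0.
gamete_self_convolution <- function(G) {
  out <- numeric(7)
  for (i in 1:4) {
    gi <- G[i]
    if (gi == 0) next
    idx <- i:(i + 3)
    out[idx] <- out[idx] + gi * G
  }
  out
}

#' Zygote frequencies under random gamete union
#'
#' Equilibrium (HWE-product) genotype frequencies implied by a gamete
#' distribution: each zygote class is the sum over ordered gamete pairs
#' whose dosages add to the class dosage, e.g.
#' Q_4A2a = 2 P_AAA P_Aaa + P_AAa^2.
#'
#' @param gam gamete distribution (AAA..aaa).
#' @return genotype distribution (6A..6a).
#' @export
zygote_freqs_from_gametes <- function(gam) {
  gam <- as_gamete_distribution(gam)
  as_genotype_distribution(gamete_self_convolution(gam))
}

#' One generation of random mating
#'
#' Offspring genotype frequencies after one round of panmixia: the gamete
#' pool of the parental population united at random (self-convolution).
#' This is the recursive-equation step; it is mathematically identical to
#' summing the 28 mating types of the transmission table. The output is
#' renormalised by its sum, an exact no-op in exact arithmetic that stops
#' floating-point sum drift from compounding (the raw convolution squares
#' any drift each generation).
#'
#' @param pop parental genotype distribution (6A..6a).
#' @param alpha double-reduction rate.
#' @return offspring genotype distribution.
#' @export
next_generation <- function(pop, alpha = 0) {
  pop <- as_genotype_distribution(pop)
  off <- gamete_self_convolution(pool_gametes(pop, alpha))
  off <- off / sum(off)
  names(off) <- GENOTYPE_LABELS
  off
}

#' Zygote frequencies one generation on, without double reduction
#'
#' Closed-form offspring frequencies R_j for one round of random mating at
#' alpha = 0, written as explicit polynomials in the parental class
#' frequencies (the closed forms published for this recursion, with the
#' duplicated heterozygote block read as its A<->a mirror, i.e. R_1A5a).
#' Identical to `next_generation(parent, 0)`; kept as an independent code
#' path so the two constructions can be cross-checked.
#'
#' @param parent parental genotype distribution (6A..6a).
#' @return offspring genotype distribution.
#' @export
reduced_zygote_freqs_alpha0 <- function(parent) {
  p <- as_genotype_distribution(parent)
  P6 <- p[[1]]; P5 <- p[[2]]; P4 <- p[[3]]; P3 <- p[[4]]
  P2 <- p[[5]]; P1 <- p[[6]]; P0 <- p[[7]]
  R6 <- (P6 + P5/2 + P4/5 + P3/20)^2
  R5 <- (1/200) * (20*P6 + 10*P5 + 4*P4 + P3) *
    (10*P5 + 12*P4 + 9*P3 + 4*P2)
  R4 <- (1/400) * (100*P5^2 + 176*P4^2 + 99*P3^2 + 16*P2^2 +
    160*P6*P4 + 360*P6*P3 + 480*P6*P2 + 400*P6*P1 + 320*P5*P4 +
    360*P5*P3 + 320*P5*P2 + 200*P5*P1 + 296*P4*P3 + 192*P4*P2 +
    80*P4*P1 + 96*P3*P2 + 20*P3*P1)
  ## the 3A3a row's published 6A x 3A3a coefficient (100) contradicts the
  ## gamete-pool expansion (2 * 1 * 1/20 = 1/10, i.e. 10 on this scale);
  ## the expansion wins
  R3 <- (1/100) * (24*P4^2 + 41*P3^2 + 24*P2^2 + 10*P6*P3 +
    40*P6*P2 + 100*P6*P1 + 200*P6*P0 + 20*P5*P4 + 50*P5*P3 +
    80*P5*P2 + 100*P5*P1 + 100*P5*P0 + 74*P4*P3 + 88*P4*P2 +
    80*P4*P1 + 40*P4*P0 + 74*P3*P2 + 50*P3*P1 + 10*P3*P0 + 20*P2*P1)
  R2 <- (1/400) * (16*P4^2 + 99*P3^2 + 176*P2^2 + 100*P1^2 +
    20*P5*P3 + 80*P5*P2 + 200*P5*P1 + 400*P5*P0 + 96*P4*P3 +
    192*P4*P2 + 320*P4*P1 + 480*P4*P0 + 296*P3*P2 + 360*P3*P1 +
    360*P3*P0 + 320*P2*P1 + 160*P2*P0)
  ## mirror of the R5 block (the published second "R_5A1a")
  R1 <- (1/200) * (4*P4 + 9*P3 + 12*P2 + 10*P1) *
    (P3 + 4*P2 + 10*P1 + 20*P0)
  R0 <- (P3/20 + P2/5 + P1/2 + P0)^2
  out <- c(R6, R5, R4, R3, R2, R1, R0)
  out <- out / sum(out)
  names(out) <- GENOTYPE_LABELS
  out
}

#' Iterate the random-mating recursion
#'
#' Applies [next_generation()] repeatedly, recording the whole trajectory.
#' Hexaploid populations never reach exact Hardy-Weinberg proportions in one
#' generation; frequencies stabilise (asymptotic HWE) after about 8-9
#' rounds of random mating.
#'
#' @param init initial genotype distribution (generation 0).
#' @param alpha double-reduction rate.
#' @param generations number of rounds of random mating (>= 0).
#' @return object of class `hex_trajectory`: a data.frame with column
#'   `generation` (0..generations) and one frequency column per genotype
#'   class; the double-reduction rate is stored in `attr(, "alpha")`.
#' @export
iterate_generations <- function(init, alpha = 0, generations = 8) {
  init <- as_genotype_distribution(init)
  alpha <- check_alpha(alpha)
  if (!is.numeric(generations) || length(generations) != 1L ||
      is.na(generations) || generations < 0 ||
      generations != round(generations)) {
    stop("generations must be a non-negative integer")
  }
  out <- matrix(NA_real_, nrow = generations + 1L, ncol = 7L)
  out[1L, ] <- init
  pop <- init
  t <- 0L
  while (t < generations) {
    pop <- next_generation(pop, alpha)
    t <- t + 1L
    out[t + 1L, ] <- pop
  }
  traj <- data.frame(generation = 0:generations, out)
  names(traj) <- c("generation", paste0("f_", GENOTYPE_LABELS))
  attr(traj, "alpha") <- alpha
  class(traj) <- c("hex_trajectory", "data.frame")
  traj
}

#' Distribution at the end of a trajectory
#' @param traj a `hex_trajectory`.
#' @return genotype distribution of the last generation.
#' @export
trajectory_endpoint <- function(traj) {
  stopifnot(inherits(traj, "hex_trajectory"))
  as_genotype_distribution(as.numeric(traj[nrow(traj), -1L]))
}

#' Iterate to asymptotic equilibrium
#'
#' Runs the random-mating recursion until the largest per-class change
#' between consecutive generations drops below `tol`, or `max_generations`
#' is reached.
#'
#' @param init initial genotype distribution.
#' @param alpha double-reduction rate.
#' @param tol convergence tolerance on the max per-class change (> 0).
#' @param max_generations iteration cap.
#' @return list with `distribution` (the near-equilibrium genotype
#'   distribution), `generations_used`, and `converged`.
#' @export
equilibrium_distribution <- function(init, alpha = 0, tol = 1e-9,
                                     max_generations = 200) {
  init <- as_genotype_distribution(init)
  alpha <- check_alpha(alpha)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  pop <- init
  for (t in seq_len(max_generations)) {
    nxt <- next_generation(pop, alpha)
    if (max(abs(nxt - pop)) < tol) {
      ## change between generations t-1 and t already below tol
      return(list(distribution = nxt, generations_used = t - 1L,
                  converged = TRUE))
    }
    pop <- nxt
  }
  warning("equilibrium not reached within ", max_generations, " generations")
  list(distribution = pop, generations_used = max_generations,
       converged = FALSE)
}

#' Write a trajectory as TSV
#'
#' One row per generation, frequencies at 12 significant digits.
#'
#' @param traj a `hex_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hex_trajectory"))
  df <- as.data.frame(traj)
  for (j in 2:8) df[[j]] <- signif(df[[j]], 12)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
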