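## Shared fixtures and independent oracles for the suite.

worked_counts <- c(29, 21, 17, 10, 10, 10, 23)        # N = 120
snp4_freqs <- c(0.4000, 0.4875, 0.1125)
truth_parent <- c(0.10, 0.05, 0.20, 0.25, 0.13, 0.10, 0.17)
truth_gametes <- c(0.30, 0.20, 0.35, 0.15)

## Random valid genotype distribution.
r_genotype <- function() {
  x <- rgamma(7, 1)
  x / sum(x)
}

r_gamete <- function() {
  x <- rgamma(4, 1)
  x / sum(x)
}

## Independent oracle for one round of random mating: explicit summation
## over the 49 ordered parental mating pairs, each contributing the
## convolution of its two single-parent gamete rows. This shares no code
## with next_generation()'s pool-then-convolve path.
mating_type_offspring <- function(pop, alpha) {
  out <- numeric(7)
  for (d1 in 6:0) {
    g1 <- gamete_distribution(d1, alpha)
    for (d2 in 6:0) {
      g2 <- gamete_distribution(d2, alpha)
      w <- pop[7 - d1] * pop[7 - d2]
      if (w == 0) next
      for (i in 1:4) for (j in 1:4) {
        k <- i + j - 1L
        out[k] <- out[k] + w * g1[i] * g2[j]
      }
    }
  }
  out
}

mean_dosage <- function(pop) sum((6:0) * pop)

## A <-> a relabelling is index reversal in the fixed 6A..6a order.
swap_alleles <- function(x) rev(unname(x))
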