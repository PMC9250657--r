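#' @keywords internal
"_PACKAGE"

## Class labels, ordered by descending A-dosage (the convention used in every
## table and file this package reads or writes).
GENOTYPE_LABELS <- c("6A", "5A1a", "4A2a", "3A3a", "2A4a", "1A5a", "6a")
GAMETE_LABELS <- c("AAA", "AAa", "Aaa", "aaa")
COLLAPSED_LABELS <- c("6A", "A_a", "6a")

## Upper bound on the double-reduction rate in hexaploids under random
## chromatid segregation.
ALPHA_MAX <- 3 / 11

#' Genotype dosage vector
#'
#' Dosages (number of copies of allele A) for the seven hexaploid genotype
#' classes, in the package's fixed 6A..6a order.
#' @keywords internal
GENOTYPE_DOSAGE <- 6:0

GAMETE_DOSAGE <- 3:0

#' Validate a hexaploid genotype frequency distribution
#'
#' A genotype distribution is a numeric vector of 7 non-negative frequencies
#' over the dosage classes 6A, 5A1a, 4A2a, 3A3a, 2A4a, 1A5a, 6a (descending
#' A-dosage), summing to 1.
#'
#' @param x numeric vector of length 7.
#' @param tol tolerance on the sum-to-one constraint.
#' @return the validated vector, named by genotype class.
#' @export
as_genotype_distribution <- function(x, tol = 1e-8) {
  x <- as.numeric(x)
  if (length(x) != 7L) {
    stop("a genotype distribution has 7 classes (6A..6a); got ", length(x))
  }
  if (any(!is.finite(x)) || any(x < -tol)) {
    stop("genotype frequencies must be finite and non-negative")
  }
  if (abs(sum(x) - 1) > tol) {
    stop("genotype frequencies must sum to 1 (sum = ", format(sum(x)), ")")
  }
  x <- pmax(x, 0)
  x <- x / sum(x)
  names(x) <- GENOTYPE_LABELS
  x
}

#' Validate a triploid gamete frequency distribution
#'
#' @param x numeric vector of length 4 over gametes AAA, AAa, Aaa, aaa
#'   (descending A-dosage), non-negative, summing to 1.
#' @param tol tolerance on the sum-to-one constraint.
#' @return the validated vector, named by gamete class.
#' @export
as_gamete_distribution <- function(x, tol = 1e-8) {
  x <- as.numeric(x)
  if (length(x) != 4L) {
    stop("a gamete distribution has 4 classes (AAA..aaa); got ", length(x))
  }
  if (any(!is.finite(x)) || any(x < -tol)) {
    stop("gamete frequencies must be finite and non-negative")
  }
  if (abs(sum(x) - 1) > tol) {
    stop("gamete frequencies must sum to 1 (sum = ", format(sum(x)), ")")
  }
  x <- pmax(x, 0)
  x <- x / sum(x)
  names(x) <- GAMETE_LABELS
  x
}

#' Validate a double-reduction rate
#'
#' The double-reduction rate alpha is bounded by 3/11 in hexaploids under
#' random chromatid segregation; the closed interval [0, 3/11] is accepted so
#' that boundary values are evaluable.
#'
#' @param alpha scalar in [0, 3/11].
#' @return the validated scalar.
#' @export
check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    stop("alpha must be a finite numeric scalar")
  }
  if (alpha < 0 || alpha > ALPHA_MAX + 1e-12) {
    stop("alpha must lie in [0, 3/11]; got ", format(alpha))
  }
  min(max(alpha, 0), ALPHA_MAX)
}

#' Validate observed genotype counts
#'
#' @param counts numeric vector of 7 non-negative counts in 6A..6a order.
#' @return named numeric vector.
#' @export
as_genotype_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 7L) {
    stop("genotype counts must have 7 classes (6A..6a); got ", length(counts))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("genotype counts must be finite and non-negative")
  }
  if (sum(counts) < 1) stop("total count must be at least 1")
  names(counts) <- GENOTYPE_LABELS
  counts
}

#' Validate collapsed three-class counts or frequencies
#'
#' Dosage-ambiguous markers collapse the five heterozygote classes into one
#' observable class, leaving three classes: 6A, any heterozygote (A_a), 6a.
#' Frequency triples (summing to ~1) are accepted as-is; tests run on them
#' use the frequency scale with an optional pseudo-N.
#'
#' @param x numeric vector of length 3 (counts or frequencies), order
#'   6A, A_a, 6a.
#' @return named numeric vector.
#' @export
as_collapsed_counts <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L) {
    stop("collapsed counts have 3 classes (6A, A_a, 6a); got ", length(x))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("collapsed counts must be finite and non-negative")
  }
  if (sum(x) <= 0) stop("total must be positive")
  names(x) <- COLLAPSED_LABELS
  x
}

## TRUE when a 3-vector looks like a frequency triple rather than counts.
is_frequency_triple <- function(x, tol = 1e-6) abs(sum(x) - 1) < tol

#' Mean A-allele frequency of a genotype distribution
#'
#' @param pop genotype distribution (7 classes, 6A..6a).
#' @return allele frequency p = mean dosage / 6.
#' @export
allele_frequency <- function(pop) {
  pop <- as_genotype_distribution(pop)
  sum(GENOTYPE_DOSAGE * pop) / 6
}
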