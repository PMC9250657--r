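---
title: "Testing asymptotic Hardy-Weinberg equilibrium and double reduction in autohexaploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing asymptotic Hardy-Weinberg equilibrium and double reduction in autohexaploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexaHWE)
```

## The transmission model

An autohexaploid carries six homologous copies of each chromosome, so a
biallelic marker has seven genotype classes, indexed throughout this
package by descending A-dosage: 6A, 5A1a, 4A2a, 3A3a, 2A4a, 1A5a, 6a.
Meiosis produces triploid gametes (AAA, AAa, Aaa, aaa). Without double
reduction, a parent of dosage $d$ transmits a gamete of dosage $g$ with
the hypergeometric probability of drawing 3 of its 6 chromosomes.
Double reduction — two sister chromatids of one chromosome ending up in
the same gamete after crossover — occurs at rate $\alpha$, bounded by
$3/11$ under random chromatid segregation, and shifts gamete mass towards
the parent-homozygous classes. `gamete_transition_matrix(alpha)` encodes
the resulting $7 \times 4$ table; each row sums to one identically in
$\alpha$ and has mean gamete dosage exactly $d/2$, so allele frequency is
conserved through meiosis.

Under panmixia the offspring genotype distribution is the
self-convolution of the population gamete pool:

$$P'_j \;=\; \sum_{g_1 + g_2 = j} G_{g_1} G_{g_2},
\qquad G \;=\; M(\alpha)^\top P,$$

where $M(\alpha)$ is the transmission matrix and $P$ the parental
genotype distribution. `next_generation()` implements exactly this.
The same offspring frequencies can be written as an explicit sum over
the 28 unordered mating types; the suite cross-checks the two
constructions to $10^{-12}$ on random inputs, and one published
closed-form coefficient (the 6A x 3A3a contribution to offspring 3A3a)
was corrected from that expansion — the convolution is exact by
construction and immune to transcription slips.

One numerical caution is built in: the raw convolution squares its
input's total mass, so any floating-point drift in the sum doubles every
generation and destroys long trajectories. `next_generation()` therefore
renormalises its output, an exact no-op in exact arithmetic.

## Asymptotic Hardy-Weinberg equilibrium

Unlike diploids, hexaploids do not reach Hardy-Weinberg proportions in
one generation: iterating the recursion contracts the genotype
distribution towards a stationary state while conserving the allele
frequency $p$. At $\alpha = 0$ the stationary distribution is the
binomial $\mathrm{Bin}(6, p)$ over dosage; with double reduction the
equilibrium shifts towards homozygote excess. From a typical starting
point the per-class change drops below $10^{-3}$ by 8-9 rounds, which is
why the tests read their "equilibrium" expectation at generation 8 by
default (`generations = 8`; the stability threshold $10^{-3}$ is this
package's choice — the stabilisation claim in the source literature
names no tolerance). `equilibrium_distribution()` offers tolerance-based
convergence instead (default `tol = 1e-9`, cap 200 generations).

## The tests

Seven-class statistics default to the count scale
$N \sum_j (o_j - e_j)^2 / e_j$, which is the scale on which chi-square
p-values are meaningful; every test also exposes
`scale = "frequencies"` (the same sum without $N$), because the
published per-marker worked-example and chrysanthemum statistics are
reproducible only on that scale. The `TestResult` records which scale
was used.

**Recursive test** (`recursive_ahwe_test`): compares the observed
frequencies with their own image after 8 rounds of the recursion,
df = 6. It is the one test with genuine power to detect a population
that has not yet converged to equilibrium, and its expectation depends
only on the data.

**Gamete-based test** (`gamete_based_ahwe_test`): fits the four gamete
frequencies by EM under the gamete-product model
($Q_{6A} = P_{AAA}^2$, $Q_{5A1a} = 2 P_{AAA} P_{AAa}$, ...) and compares
observed with expected. `expected_mode = "fitted"` uses the fitted
products directly (the natural goodness-of-fit reading);
`"equilibrium"` carries the fit a further 8 rounds before comparing,
which is the construction under which the published worked-example value
is reproducible. Degrees of freedom are not exactly known for this
family; the package defaults to 5 (7 classes, minus one for the
constraint, minus one effective parameter) with 6 available.

**Double-reduction test** (`double_reduction_test`): fits the parental
genotype frequencies by EM under the $\alpha = 0$ transmission model and
compares observed offspring with expected. A structural fact shapes the
default here: every transmission row at $\alpha > 0$ is a convex
combination of the $\alpha = 0$ rows, so any gamete pool produced *with*
double reduction is exactly reproducible by some double-reduction-free
parent. The literal one-generation expectation
(`expected_mode = "fitted"`) therefore reproduces the observations
almost perfectly whatever the true $\alpha$, and the test has
asymptotically no power — the suite demonstrates this on exact
$\alpha = 0.25$ data. The default (`expected_mode = "equilibrium"`)
instead reads the expectation at generation 8 of the fitted model, i.e.
the no-double-reduction asymptotic equilibrium, against which
double-reduction-induced homozygote excess *is* visible. Its null is "the
population sits at the $\alpha = 0$ equilibrium"; under that null the
statistic behaves like chi-square with about 5 df (one parameter, the
allele frequency, is effectively estimated), and the package defaults to
df = 5.

**Parental-equilibrium LR test** (`parental_ahwe_lr_test`): alternative
= free parental frequencies at $\alpha = 0$; null = parent constrained
to gamete products with $\alpha$ free; LR referred to $\chi^2_1$ and
floored at zero. The same structural fact applies: one round of random
mating restores gamete-product form exactly, so from a single offspring
sample the constrained family fits (numerically to KL $\sim 10^{-13}$)
anything the free family fits, and the test's rejection rate stays near
zero under both hypotheses. It is included as specified, calibrated
(its false-positive rate is well below nominal) but essentially
powerless; the recursive test is what carries power against
non-equilibrium populations.

**Collapsed-marker variants**: low-resolution genotyping cannot separate
the five heterozygous dosages, leaving three observable classes
(6A, A_a, 6a). The allele-based test expects
$(p^6,\, 1 - p^6 - q^6,\, q^6)$ with $p$ estimated either by the
midpoint rule $p = f_{6A} + f_{A\_a}/2$ (default; it reproduces the
published chrysanthemum expectations) or by multinomial ML. The
collapsed recursive test expands the heterozygote mass uniformly over
dosages 1-5 — a choice that conserves the midpoint allele frequency —
iterates 8 rounds at $\alpha = 0$, and collapses back; both run on the
frequency scale with df = 2 by default, the combination that reproduces
the published per-marker chi-squares and p-values. The collapsed
double-reduction test models the parent as $\mathrm{Bin}(6, p)$ and the
data as the collapse of one round of mating at rate $\alpha$; `mode =
"lr"` tests $\alpha = 0$ against $\alpha$ free (df = 1), while `mode =
"gof"` reports how well the fitted $(p, \alpha)$ model fits (df = 2) —
the reading under which the published marker classifications reproduce.

## Estimation and identifiability

All EMs maximise the multinomial log-likelihood
$\sum_j N_j \log e_j(\theta)$, with mixture classes split by posterior
weight in the E-step and closed-form frequency updates in the M-step
(gamete usage over $2N$ slots, parental-slot usage over $2N$, founding
gametes over $4N$ for the joint model). Convergence is an absolute
log-likelihood change below `tol` (default $10^{-9}$, cap $10^4$
iterations); the log-likelihood is asserted non-decreasing every
iteration. One moment-based start (binomial gamete frequencies at the
observed allele frequency; the observed frequencies for the parental
model) is always used, plus `n_restarts - 1` random simplex starts.

Two identifiability facts matter for interpretation:

* The parental seven-class frequencies enter the offspring distribution
  only through the four-class gamete pool, so the parental MLE is a
  *set*; `em_parental_genotypes_alpha0()` returns the representative its
  EM converged to, and only the fitted offspring frequencies are
  identified.
* In the joint model (`em_joint_gamete_alpha()`), $\alpha$ rides a flat
  likelihood ridge: re-optimising the gamete frequencies at any fixed
  $\alpha \in [0, 3/11]$ recovers the same maximum (profile KL
  $\sim 10^{-6}$ or below on exact data). A single offspring generation
  cannot identify the double-reduction rate under an equilibrium parent.
  The reported $\hat\alpha$ is the ridge point the optimiser reaches
  from its start; in repeated sampling at $N = 100$ its mean sits near
  mid-range ($\approx 0.14$-$0.15$) regardless of the truth, with
  standard deviation around $0.1$. Published recoveries of $\alpha$ from
  such data should be read with this in mind. Because the EM crawls
  along this ridge, the joint fit finishes with a bounded quasi-Newton
  polish from the EM point (`polish = TRUE`); the EM phase preserves the
  monotone-likelihood property and the polish only ever improves the
  likelihood.

## The Monte-Carlo engine

`run_power_study()` and `run_estimator_study()` simulate multinomial
offspring counts per (alpha, N) cell and tabulate rejection rates or
estimator summaries. The truth is a parental genotype distribution
(or gamete frequencies whose products form the parent). Two generative
designs are exposed: `offspring_at = "next_generation"` (default; one
round of random mating separates truth from sample) and
`"equilibrium"` (sampling at the generation-8 state of the truth's own
trajectory at the cell's $\alpha$). The second is the design under
which the double-reduction test's null actually holds, and the one the
package's calibration study uses: at $N = 100$ and 1000 replicates its
false-positive rate is about 0.06-0.07 at the 5% level, and its power
against $\alpha = 1/7$ about 0.19. Exact parental frequencies are used
(no multinomial pre-sampling of parents) — the lower-variance choice;
replicate counts default to 1000 and are configurable. All randomness
comes from one master seed with deterministic per-cell substreams, so a
study is bit-reproducible from its config.

The same engine doubles as the synthetic-data generator for the test
suite. What it emulates is exactly the model: clean multinomial sampling
from a known transmission process. Real dosage data add genotype-calling
error, dosage uncertainty from finite read depth, null alleles and
population structure, none of which are modelled; green tests here say
the machinery is correct under the model, not that the model captures
any particular data set.

## Numerical and design choices

* Dosage indexing is descending-A everywhere (6A first); allele
  relabelling is index reversal, and every operation is tested to
  commute with it.
* $\alpha$ is accepted on the closed interval $[0, 3/11]$ so boundary
  values are evaluable; estimates are clipped to it and boundary fits
  flagged.
* Zero expected classes follow the 0/Inf rule: zero observed
  contributes 0, positive observed flags an infinite statistic. Tiny
  expected frequencies (e.g. $10^{-6}$-scale homozygote expectations at
  extreme allele frequencies) are deliberately *not* floored or pooled —
  the large published collapsed-marker statistics require keeping them.
* EM tolerances: the defaults above; the simulation studies pass
  `tol = 1e-7`-$10^{-8}$ and tighter iteration caps for throughput, at
  problem sizes (500-1000 replicates, $N = 100$-$400$) chosen so the
  full acceptance computation completes in minutes on one CPU.
* The worked-example reproduction fixes $\alpha = 0$ in the recursion
  (the source example names no rate).

## Known limitations

Hexaploid-specific throughout: no other ploidy, no sex-specific
transmission, no selection/drift/mutation/migration, no two-locus
extension, and no genotype-likelihood input — dosage calls are taken as
known. The parental-equilibrium LR test and the fitted-mode
double-reduction test are included for completeness but are structurally
powerless from single-generation data (see above); inference about
double reduction from natural populations needs either multi-generation
data or external constraints on the parental distribution.
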