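# hexaHWE

Statistical machinery for testing Hardy-Weinberg equilibrium and double
reduction at biallelic markers in autohexaploid populations — sweetpotato,
chrysanthemum, kiwifruit and other 2n = 6x species with polysomic
inheritance.

Hexaploids never reach exact Hardy-Weinberg proportions after one round of
random mating. A parent of A-dosage *d* transmits a triploid gamete of
dosage *g* with hypergeometric probability, perturbed by the
double-reduction rate α (bounded by 3/11 under random chromatid
segregation), and the offspring genotype distribution is the
self-convolution of the population gamete pool:

    P'_j = Σ_{g1+g2=j} G_{g1} G_{g2},   G = M(α)' P

Iterating this recursion, the seven genotype frequencies stabilise only
after about 8–9 generations — *asymptotic* HWE (aHWE), a binomial dosage
distribution when α = 0 and a homozygote-enriched state otherwise. The
package implements this transmission model, chi-square and
likelihood-ratio tests of aHWE and of double reduction built on it
(including three-class variants for dosage-ambiguous markers, whose five
heterozygote classes a low-resolution genotyping platform cannot
separate), EM estimators of gamete and parental genotype frequencies, and
a seeded Monte-Carlo engine for power and calibration studies.

## Worked example

A sample of 120 hexaploid individuals with genotype counts
(6A..6a) = (29, 21, 17, 10, 10, 10, 23):

```r
library(hexaHWE)
counts <- c(29, 21, 17, 10, 10, 10, 23)
recursive_ahwe_test(counts)
#> recursive aHWE test
#>   chi-square/LR = 799.364, df = 6, p = 2.113e-169  [counts scale, n = 120]
#>               6A   5A1a   4A2a    3A3a    2A4a    1A5a       6a
#> observed 0.24170 0.1750 0.1417 0.08333 0.08333 0.08333 0.191700
#> expected 0.03274 0.1507 0.2893 0.29650 0.17120 0.05279 0.006791
```

The observed distribution is strongly U-shaped (homozygote excess); its
own generation-8 image under the recursion is near-binomial, so the
sample deviates massively from aHWE. The EM fit of the four gamete
frequencies under the equilibrium product model:

```r
em_gamete_frequencies(counts, seed = 1)
#> EM fit (gamete_frequencies)
#>   gamete_freq: 0.42156 0.1596 0.11196 0.30688
#>   logLik -243.6548 after 19 iterations (converged: TRUE, restarts: 3)
```

For a dosage-ambiguous marker with observed class frequencies
(6A, any-heterozygote, 6a) = (0.4000, 0.4875, 0.1125):

```r
allele_based_ahwe_test_collapsed(c(0.4000, 0.4875, 0.1125))
#> allele-based aHWE test (p by midpoint)
#>   chi-square/LR = 7.69575, df = 2, p = 0.02133  [frequencies scale, n = 100]
#>               6A    A_a       6a
#> observed 0.40000 0.4875 0.112500
#> expected 0.07117 0.9268 0.002044
```

The allele frequency p = 0.4 + 0.4875/2 = 0.64375 gives expected class
frequencies (p⁶, 1 − p⁶ − q⁶, q⁶); the marker rejects aHWE at the 5%
level.

A command-line wrapper ships at `inst/cli/hexahwe.R`:

```sh
Rscript inst/cli/hexahwe.R test --input inst/extdata/worked_example.tsv \
    --mode recursive --scale frequencies
Rscript inst/cli/hexahwe.R trajectory \
    --init 0.1,0.05,0.2,0.25,0.13,0.1,0.17 --alpha 0 --generations 12 \
    --out trajectory.tsv
```

See the methods vignette (`vignettes/hexaploid-hwe-methods.Rmd`) for the
model, the test constructions and their operating characteristics, and
two identifiability results that shape what these tests can and cannot
detect from single-generation data.

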