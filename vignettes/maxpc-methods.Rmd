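---
title: "Testing association and maternal effects in case-parent trios with max_PC"
author: "triadPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing association and maternal effects in case-parent trios with max_PC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadPC)
```

## The design and the statistic

A case-parent trio consists of an affected child and both parents,
genotyped at `q` biallelic SNPs. Writing `M`, `F`, `C` for the number of
copies of a counted allele carried by mother, father and child at one
locus, two difference scores summarize each trio:

* `X = 2C - F - M`, the difference between the child and the
  *complement* — the pseudo-individual carrying the parental alleles
  that were **not** transmitted (count `F + M - C`). Under no
  association, transmission is symmetric and `E[X] = 0`, whatever the
  population structure, because the comparison is internal to each
  family.
* `Y = M - F`, the mother against the father as her matched control.
  Under *mating symmetry* — the assumption that (mother, father)
  genotype pairs are exchangeable in the source population — `E[Y] = 0`
  unless the maternal genotype itself influences the child's phenotype
  (a maternally mediated effect, e.g. through the intrauterine
  environment).

The bivariate observation `Z = (X, Y)'` therefore has mean zero under
the joint null hypothesis of *no association and no maternal effect*.
At one locus with `n` complete trios, let `S` be the sample covariance
matrix of `Z` (denominator `n - 1`), with eigenpairs
`(lambda_1, e_1)`, `(lambda_2, e_2)`, `lambda_1 >= lambda_2 >= 0`. With
`zetaBar_k = e_k' Zbar` the mean of the k-th sample principal
component, the locus statistic is

    PC = n (zetaBar_1 + zetaBar_2)^2 / (lambda_1 + lambda_2)

Because `e_1 + e_2` has squared `S`-norm `lambda_1 + lambda_2`, `PC` is
a studentized squared projection of the mean, asymptotically central
chi-square with 1 df under the joint null — a property the package
verifies by simulation (`locusPC`, and the Kolmogorov–Smirnov check in
the test suite). Across `q` loci the test statistic is the maximum,
`max_PC = max_l PC^(l)`, computed per locus on complete cases so that
missing genotype calls at some SNPs cost only those SNPs' trios.

The comparator `max_Z^2` applies the same maximum to the
one-dimensional squared standardized sums `Z^2 = (sum d)^2 / sum d^2`
with `d = X` (association channel) or `d = Y` (maternal channel). It
tests one channel at a time; `max_PC` pools both into a single test.

```{r one-locus}
locusPC(c(1, -1, 1, 1, 0, 1), c(0, 1, -1, 0, 1, 1))
```

## Permutation calibration

The loci are correlated through linkage disequilibrium, so the null
distribution of the maximum is obtained by permutation rather than by a
Bonferroni-type bound. For each permutation and each trio
independently, with probability 1/2:

* the case and complement labels are swapped, which negates that trio's
  `X` at every locus (the complement's count is `F + M - C`);
* the mother and father labels are swapped, which negates `Y` and
  leaves `X` unchanged.

Both swaps are exchangeability operations under the joint null, and
both are needed: the case/complement swap alone nulls only the
association channel. Flips are drawn at the trio level and shared
across loci, preserving the between-locus dependence that the maximum
is calibrated against; per-locus flipping would destroy the implicit
multiplicity correction. The reported `p` is the proportion of permuted
maxima *strictly larger* than the observed one, so `p = 0` is possible;
`addOneCorrection = TRUE` switches to `(1 + #larger)/(B + 1)` for users
who prefer an estimate bounded away from zero.

```{r permute}
set.seed(1)
trios <- sampleAffectedTrios(populationModel(), diseaseScenario(), 100)
diffs <- computeDiffVectors(trios)
permuteStat(diffs, "maxPC", permutationPlan(1000, 100, seed = 2))
```

## Numerical conventions

* **Covariance denominator.** `S` uses `n - 1`. Using `n` would rescale
  every `PC` by the same factor in observed and permuted data, leaving
  p-values untouched; `n - 1` is the conventional estimator and is what
  the accessors report.
* **Eigenvector signs.** Eigenvectors are defined up to sign, and `PC`
  depends on the *relative* sign of `e_1` and `e_2` through
  `(e_1 + e_2)' Zbar`. Each eigenvector is canonicalized so its first
  nonzero component is positive; the identical convention is applied to
  observed and permuted data, which is what makes the permutation
  calibration valid. Flipping the convention globally
  (`signConvention = "negative"`) negates both vectors and provably
  changes nothing — the package asserts this. Note that flipping only
  *one* eigenvector would genuinely change the statistic (it replaces
  the projection direction `e_1 + e_2` by the orthogonal `e_2 - e_1`);
  a convention must therefore fix both signs jointly, as done here.
* **Eigenvalue ties.** When `S` is isotropic (equal variances, zero
  covariance) every direction is an eigenvector; the coordinate axes
  are used, giving the projection direction `(1, 1)/sqrt(2)`. The same
  tie rule is applied everywhere, including the brute-force oracle in
  the tests.
* **Degenerate loci.** If `lambda_1 + lambda_2 = 0` there is no
  variation and no evidence; `PC := 0` and the locus is flagged. Loci
  that are monomorphic in `(X, Y)` or have fewer than 2 complete trios
  are excluded from the maximum with a message. The usable-locus set is
  decided from flip-invariant quantities (complete counts and sums of
  squares), so observed and permuted maxima always range over the same
  loci.
* **Missing data.** A cell is complete only when all three genotypes
  are present; `X` and `Y` are evaluated per locus on complete cases,
  and per-locus trio counts are reported. Masking one trio at one locus
  changes that locus's statistic only (asserted bit-exactly in the
  tests).
* **Vectorized permutation.** Sign flips leave sums of squares
  unchanged, so all permutations need only three
  `(B x n) (n x q)` matrix products plus an elementwise closed-form
  2x2 eigensolution; the observed statistic is the `B = 1` identity
  flip, guaranteeing identical conventions on both paths.

## The trio simulator

The generator reproduces a classic candidate-gene setting and doubles
as the package's fixture source:

* **Markers.** 20 SNPs evenly spaced across 100 kb. Allele frequencies
  drawn uniform on (0.1, 0.9); adjacent-pair standardized
  disequilibrium `D'` uniform on (-0.9, 0.9), converted to raw `D`
  through the Lewontin bound so every draw is feasible, and haplotypes
  generated left-to-right by the implied first-order Markov chain.
  Frequencies, LD and the disease position are redrawn for every
  replicate of a study, so estimated rates average over region
  configurations.
* **Disease allele.** A latent biallelic locus at a uniform position,
  allele `D` at frequency 0.1, introduced on a single founder
  ("ancestral") haplotype — itself one draw of the same Markov chain —
  1,000 generations ago (500 in the second admixture subpopulation).
  Each present-day `D` haplotype decays by at most one crossover per
  meiosis with probability `recombRate * regionKb` (default 1 cM/Mb,
  i.e. 0.001 per meiosis), the non-`D` side being replaced by a fresh
  background haplotype. The disease SNP itself is never emitted: only
  the 20 markers are observed.
* **Trios.** Parents are drawn from a present-day pool of 10,000
  haplotypes; each transmits one (possibly recombined) haplotype.
  Affection probability is `baseline x R(genotype)` with relative risks
  `R_1`, `R_2` for one and two copies of `D`, acting through the
  child's genotype (association), the mother's (maternal), or their
  product (joint); trios are retained until `N` affected children are
  collected. Dominant means `R_1 = R_2 = 2`, recessive `R_1 = 1,
  R_2 = 2`, baseline 0.01.
* **Admixture.** Two independently parameterized subpopulations
  (`D` frequencies 0.1 / 0.2, baselines 0.01 / 0.05, different founder
  haplotypes and ages) mixed 30/70 at the last generation; each trio's
  parents come from a single subpopulation. This is the classic
  stratification setting that within-family tests must tolerate, and
  the type I error stays nominal there.

Choices the underlying description leaves open, fixed once here: the
recombination map (1 cM/Mb, uniform, at most one crossover per region
per meiosis), the pool size (10,000 haplotypes per subpopulation), the
age of `D` in the homogeneous population (1,000 generations), and
within-subpopulation mating under admixture. All are constructor
arguments.

What the generator does *not* emulate: genotyping error, non-uniform
marker spacing, recurrent mutation, selection, X-linked loci, or
phase-known haplotypes. Passing tests therefore demonstrate
correctness of the statistics and calibration of the permutation under
this generative model, not robustness to artifacts of real genotype
data beyond random missingness.

## Study scale and what the simulations show

`runCell()` / `powerStudy()` estimate rejection rates over replicated
simulations. The desk-scale profile used by the test suite and the
acceptance script is 1,000–2,000 replicates with 500 permutations each
(type I error cells use 2,000 replicates; power cells 1,000); full-scale
runs (10,000 x 1,000) are a flag away. One master seed spawns
per-replicate substreams — one for the data, one for the flips — so any
execution order reproduces identical results.

At these settings the type I error of `max_PC` at `alpha = 0.05` is
nominal in both homogeneous and admixed populations, the chi-square(1)
approximation of the single-locus `PC` passes a KS test at `n = 500`,
and power increases with sample size, with the dominant model at least
as powerful as the recessive one.

## Known limitations

* Under this generative model the per-marker signal is analytically
  bounded: with relative risk 2 and `D` frequency 0.1, the transmitted
  haplotype of an affected child carries `D` with probability 0.168
  against 0.1 for the untransmitted one, so the mean of `X` at a marker
  cannot exceed `2 x 0.068` times the ancestral-versus-background
  allele contrast, before recombination decay and the marker's own
  variance are paid. Power at `N = 100` is correspondingly modest
  (about 0.1–0.15 at desk scale, rising with `N`). Published power
  figures for this design that approach the theoretical power of
  testing the disease locus itself with a perfect marker are not
  reachable when the disease SNP is latent, whatever recombination
  rate, pool size or decay time is chosen; the package reports what the
  stated model actually yields.
* When the joint null is rejected, `max_PC` does not say *which*
  channel drove the rejection; the per-channel `max_Z^2` tests serve as
  follow-up. With a child effect present, parent-of-origin effects can
  mimic a maternal effect in `Y`; the package does not attempt to
  disambiguate them.
* The maternal channel leans on mating symmetry; populations with
  strong assortative mating violate it and `Y`-based inferences are
  then biased. The association channel `X` needs no such assumption.
* `p = 0` is a possible permutation outcome under the default strict
  inequality; for reporting, consider `addOneCorrection = TRUE` or more
  permutations.
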