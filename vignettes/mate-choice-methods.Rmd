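---
title: "Testing MHC-dependent mate choice with mhcmate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing MHC-dependent mate choice with mhcmate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mhcmate)
```

## Overview

`mhcmate` analyses female mate choice with respect to the major
histocompatibility complex (MHC) in species where MHC genes are
multi-locus and co-amplifying, so that each individual carries an
unresolvable *pooled set* of alleles per gene class rather than a
diploid genotype at known loci. The study design it targets is
pedigree-based: each offspring has a genetically assigned father and a
*candidate pool* of males that were present in (or near) the mother's
social group in the conception year. The question is whether the
realised father is a non-random draw from that pool with respect to his
MHC constitution, and whether the strength of that preference depends on
the mother's genotype at a chemosensory receptor gene (TAAR).

The package provides four inferential layers, each usable on its own:

1. **MHC indices** on pooled allele sets (`mhc_index()` and friends).
2. A **candidate-pool randomization test** (`mc_randomization_test()`)
   with an exact enumeration oracle for small designs.
3. A **binomial GLMM** over (offspring × candidate) rows with a
   parametric-bootstrap likelihood-ratio test
   (`fit_choice_glmm()`, `lrt_parametric_bootstrap()`,
   `taar_interaction_test()`).
4. An **amplicon genotyping** workflow (entropy-based allele calling
   with chimera, homology and Mendelian filters) and a permutation test
   of **linkage disequilibrium** between multi-allele loci
   (`ld_mc_test()`, `ld_screen()`).

A synthetic population generator (`generate_population()`,
`simulate_choices()`) with a tunable preference mechanism supports
calibration and power studies; `run_full_analysis()` chains everything.

## The five MHC indices

For a female allele set $F$ and male allele set $M$ (per gene class),
with $d(a,b)$ the amino-acid distance between translated alleles:

* **MALDis** — male allelic dissimilarity: $|M \setminus F|$, the number
  of male alleles the female does not carry.
* **CALDis** — couple allelic distance: $|M \,\triangle\, F|$, the size
  of the symmetric difference.
* **muAADis** — mean amino-acid distance over the unshared alleles. The
  default `mode = "within_symdiff"` averages $d$ over all unordered
  pairs within $M \triangle F$; `mode = "cross"` averages over
  $(F\setminus M) \times (M\setminus F)$ pairs. Both modes are undefined
  (`NA`) when fewer than two pairable alleles remain (for example, a
  couple with identical sets), and such couples are excluded from means
  downstream — consistently in the observed statistic and in every
  randomized replicate.
* **MALDiv** — male allelic diversity: $|M|$.
* **MAADiv** — male amino-acid diversity: mean $d$ over unordered pairs
  within $M$.

The first three are *dissimilarity* indices (they involve the mother's
genotype); the last two are *diversity* indices (father-only). All five
are exercised against brute-force oracles in the test suite.

```{r}
cat <- generate_allele_catalog("MHC1", n_alleles = 12, aa_length = 30, seed = 1)
D <- aa_distance_matrix(cat)
f <- c("MHC1-01", "MHC1-03", "MHC1-07")
m <- c("MHC1-03", "MHC1-05", "MHC1-09", "MHC1-11")
c(MALDis = maldis(f, m), CALDis = caldis(f, m), MALDiv = maldiv(m))
mu_aadis(f, m, D = D)
```

## The candidate-pool randomization test

The randomization test asks whether the mean index over the real
couples could have arisen by uniform sampling from the candidate pools.
In each of `B` replicates, one male is drawn uniformly and independently
per offspring from that offspring's *genotyped* candidates (the true
father always included), the index is computed against the mother, and
the replicate mean recorded. The two-tailed p-value counts replicate
means at least as far from the centre of the simulated distribution as
the observed mean, with the add-one correction
$p = (1 + \#\{\text{as extreme}\})/(B+1)$ so that $p$ is never zero and
the test is exact-level. Inclusion rules (father genotyped; mother
genotyped for dissimilarity indices; at least one genotyped candidate)
are applied before randomization and reported in the `dropped` field.

`exact_enumeration_test()` computes the same distribution *exactly* by
convolving the per-offspring value distributions; it is feasible when
the product of pool sizes is modest and serves as the oracle for the
Monte Carlo version. The default `B = 1e5` is a statistical choice —
the Monte Carlo standard error of $p \approx 0.05$ is then about
$7\times10^{-4}$ — not a computational ceiling; raise it freely for
publication-grade p-values.

## The mixed model and its bootstrap tests

The GLMM view expands each choice event into one row per genotyped
candidate, with `CHOSEN` indicating the realised father:

```
CHOSEN ~ MHC_INDEX + (1|COLONY) + (1|YEAR) + (1|CANDIDATEFATHER) + (1|MOTHER)
```

fitted as a binomial GLMM with `lme4::glmer`. Because the likelihood
surface with four crossed, often near-zero random intercepts is
expensive, the default approximation is `nAGQ = 0` (`approx =
"pirls"`); `approx = "laplace"` is available when accuracy of the
variance components matters more than speed.

P-values for fixed effects come from a **parametric bootstrap LRT**
(`lrt_parametric_bootstrap()`): the null model simulates new responses
(`use.u = FALSE`, i.e. re-drawing the random effects), both models are
refitted, and the observed deviance difference is ranked among the
bootstrap differences with the add-one correction. This avoids the
asymptotic chi-square, which is unreliable here because the index
enters at the row level while choices are made at the pool level.

Two practical devices are worth knowing:

* **Early stopping** (`alpha_stop`): with the add-one correction, the
  test rejects at level $\alpha$ iff the number of bootstrap
  exceedances $k$ satisfies $k \le \lfloor \alpha(n_{boot}+1)\rfloor -
  1$. Since $k$ only grows, the replication loop can stop as soon as
  that bound is exceeded; the accept/reject decision is provably
  identical to the full run and the reported p-value becomes a
  conservative upper bound (printed as `p <=`). This is how the
  calibration studies in the test suite keep hundreds of bootstrap
  tests affordable.
* **Slope confidence intervals** (`slope_bootstrap_ci()`): a parametric
  bootstrap of the fixed-effect estimate. The default `type = "basic"`
  interval reflects the bootstrap quantiles around the estimate, which
  corrects the systematic downward shift of the bootstrap distribution
  that arises when random-effect variances are estimated near zero;
  `type = "percentile"` is available for comparison.

`taar_interaction_test()` augments the table with the mother's receptor
zygosity (`add_taar_factor()`) and bootstrap-tests the
`MHC_INDEX:TAAR` interaction — the hypothesis that heterozygous and
homozygous mothers differ in preference strength.

### What the slope estimates — and what it does not

In the synthetic generator, a preference of strength $\beta$ means the
father is drawn from the pool with probability proportional to
$\exp(\beta \cdot \text{index})$ — a *conditional logit* (softmax
within pool). The row-level binomial GLMM is not that model: it treats
rows as independent Bernoulli trials, so its `MHC_INDEX` coefficient is
an *attenuated* estimate of the generating $\beta$, with the
attenuation depending on pool-size distribution and index variance. In
our calibration studies with realistic pool sizes the attenuation is
mild (mean estimates within about 0.05–0.1 of the truth at
$\beta = 0.5$), and the *test* of $\beta = 0$ is exactly calibrated
regardless — under the null the two models coincide. But users who
need an unbiased effect size should fit a pool-stratified conditional
logit (for example via `survival::clogit` or `mclogit`) on the same
table; the GLMM slope should be read as a direction-and-significance
summary, not a structural parameter. The bootstrap CI covers the GLMM's
own estimand; its coverage of the generator's $\beta$ is approximate to
the extent the attenuation is small.

## Amplicon genotyping

`simulate_reads()` produces tagged amplicon reads (barcode + primer +
insert) with substitution errors and template-switching chimeras. The
calling workflow is:

1. `demultiplex_and_trim()` — exact barcode/primer matching; reads with
   corrupted tags are discarded.
2. `filter_chimeras()` — reference-free: a read is flagged when its
   best prefix-parent and best suffix-parent among abundant sequences
   explain it better (with an abundance skew requirement) than any
   single parent.
3. `homology_filter()` — translated identity to a reference amino-acid
   set must reach `min_identity`, with stop codons and frame breaks
   rejected.
4. `call_alleles()` — oligotyping: columns of the pooled read alignment
   with Shannon entropy above `entropy_threshold` (default 0.2 nats)
   define oligotypes; per-individual alleles require `min_reads` and
   `min_fraction` support, and alleles seen in fewer than
   `min_individuals_per_allele` individuals are removed (set this to 1
   for error-free data such as positive controls).
5. `mendelian_check()` — every offspring allele must occur in mother or
   father; violations are reported per trio. `repeatability()` compares
   duplicate runs by Jaccard and exact-match rates.

## Linkage disequilibrium

`ld_mc_test()` tests association between two loci whose "genotypes" are
arbitrary labels (diploid pairs, pooled sets): the statistic is the
exact log-probability of the observed contingency table under fixed
margins, and the null distribution is generated by permuting one
locus's labels across individuals. `ld_screen()` applies it to all
pairs of a set of loci (for example TAAR genes). The permutation count
is again purely a precision choice; the defaults resolve p-values to
about $10^{-4}$.

## A calibration study in six lines

```{r, eval = FALSE}
pop <- generate_population(seed = 1)
sim <- simulate_choices(pop, preference_spec("MALDiv", beta = 0.5),
                        n_offspring = 133, seed = 2)
tab <- build_choice_table(sim$events, pop$genotypes$MHC1, "MALDiv")
fit <- fit_choice_glmm(tab)
lrt_parametric_bootstrap(tab, n_boot = 999, seed = 3)
mc_randomization_test(sim$events, pop$genotypes$MHC1, "MALDiv", seed = 4)
```

`run_full_analysis()` wraps this, adds genotype masking (only a
fraction of candidates are typically genotyped in the field), the LD
screen, and TSV/JSON outputs, and is driven by a plain list or a YAML
file; see `?run_full_analysis` and the README for a worked example.

## Limitations

* The GLMM slope is attenuated relative to the conditional-logit
  generating parameter (see above); significance tests are unaffected.
* The randomization test conditions on the *observed* candidate pools;
  it cannot detect preferences expressed through pool formation itself.
* muAADis is undefined for couples sharing (almost) all alleles; in
  designs with very low MHC diversity many couples may drop out.
* The chimera filter is reference-free and abundance-based; at very low
  depth (tens of reads per individual) its parent-abundance assumptions
  weaken.
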