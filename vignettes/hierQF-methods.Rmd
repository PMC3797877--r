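---
title: "Inferring past selection from hierarchical Q-F comparisons: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring past selection from hierarchical Q-F comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Widespread Alpine plants often show strong neutral molecular structure among
phylogeographic regions — the genetic footprint of glacial survival in
isolated refugia — and further structure among populations within regions,
formed during postglacial recolonisation. A common-garden experiment turns
this into a quantitative-genetics question: when plants from many
populations are grown in one environment, among-origin trait differences are
genetic, and their hierarchical partitioning can be compared with neutral
expectation. `hierQF` implements that comparison:

* **Q indices.** Nested random-model variance components
  (region / population-in-region / seed-family / residual) feed the
  hierarchical analogues of $Q_{ST}$:
  $$Q_{RT} = \frac{\sigma^2_R}{\sigma^2_R + 2(\sigma^2_P + V_A)}, \qquad
    Q_{SR} = \frac{\sigma^2_P}{\sigma^2_P + 2 V_A},$$
  with $V_A = k\,\sigma^2_F$ the within-population additive variance
  recovered from the seed-family component.
* **F' indices.** A three-level AMOVA on codominant microsatellites gives
  $F_{RT}$, $F_{SR}$, $F_{ST}$; each is standardized by its maximum
  attainable value given the observed within-population diversity
  (allele recoding), plus Hedrick's closed-form $G'_{ST}$.
* **Inference.** Jackknife-over-populations 95% intervals on both sides;
  $Q$ above the matching $F'$ interval indicates diversifying selection,
  below it unifying selection, overlap is compatible with drift alone.
* **Local adaptation.** Trait–elevation Pearson correlations on two-stage
  population means with sequential Holm–Bonferroni correction, and G tests
  on phenological-state censuses.

# Model and estimators

## Nested variance components

The phenotype model for unclipped (control) plants is
$y_{rpfi} = \mu + a_r + b_{p(r)} + c_{f(p)} + \varepsilon_{i}$, all effects
independent Gaussian. Two estimation routes are provided and
cross-checked:

* `estimateAnova()` — method of moments on unweighted means. Family means,
  population means (unweighted over families) and region means (unweighted
  over populations) give nested sums of squares whose expectations are
  inverted with harmonic-mean coefficients (plants per family, families per
  population, populations per region). On balanced data this reproduces the
  classical nested ANOVA estimator exactly; on unbalanced data it is the
  standard unweighted-means approximation. Negative solutions are truncated
  to zero *after* back-substitution and flagged — the indices require
  non-negative components, and a published $Q_{RT}=0.000$ is exactly what
  truncation produces.
* `estimateReml()` — REML for the same model, delegated to `lme4::lmer`
  (with a tight `bobyqa` tolerance so that the balanced-case equality with
  the moment estimator holds to $10^{-6}$, the package's cross-validation
  of both routes). REML is the recommended route for strongly unbalanced
  real data.

The initial-size covariate (rosette diameter at transplanting) is handled
by **pre-residualization**: the trait is replaced by the residuals of an
ordinary least-squares fit on the covariate plus the trait grand mean. A
joint mixed-model fit with the covariate as a fixed effect is the main
alternative; pre-adjustment was chosen because it keeps the random-model
estimator closed-form and testable, and with the slope shared across
origins the two differ only in how uncertainty of the slope propagates —
negligible at this design size. Power transforms
(`powerTransform()`, canonical exponents 0.656 / 0.620 / 0.331 for leaf
counts, flower counts and biomass) can be applied before estimation to
improve residual normality.

## Q conventions

The hierarchical $Q_{RT}$ denominator is a genuine modelling choice: the
`total_within` convention (default) counts all genetic variance below the
region level ($\sigma^2_P + V_A$) as the within-group term, the `pooled`
convention uses $V_A$ alone. Published studies rarely state which is used,
so `runPipeline()` reports both side by side rather than hiding the
ambiguity; classification uses the default. The family-structure multiplier
defaults to half sibs ($k = 4$): seed families are open-pollinated maternal
families of a self-incompatible outcrosser, so full sibship is the
exception. `full_sib` ($k=2$) and `broad_sense` ($k=1$) are provided for
sensitivity analysis.

## AMOVA and standardization

Each diploid individual contributes two allele copies; the distance is
allele identity (0/1, infinite-allele style), not repeat-length based,
because the standardized indices are defined for identity-based AMOVA. Sums
of squares at the three levels are converted to components per locus with
sample-size coefficients that accommodate unequal population and region
sizes and per-locus missingness (code 0); components are summed across loci
**before** the ratios are formed (ratio-of-sums, not mean-of-ratios, the
convention that makes multi-locus estimates consistent). Negative
components are retained in the sums — truncating them would bias the sums —
but reported F statistics are clamped to $[0,1]$ with the unclamped value
kept.

Standardization recodes alleles so that no two recoding units share a
code: per population for $F'_{ST}$ and $F'_{SR}$, per region for
$F'_{RT}$ (populations within a region keep shared codes). Recoding acts on
the per-locus count matrices, which are sufficient statistics for
identity-distance AMOVA, and the result is checked in the tests against an
explicit relabel-the-raw-data oracle. The region-level scheme for
$F'_{RT}$ is a stated convention of this package: hierarchical recoding is
not standardized in the literature. One corner is worth knowing: if
populations share no alleles even within regions, the recoded (maximal)
$F_{RT}$ is legitimately zero — region membership explains nothing beyond
population identity — so $F'_{RT}$ is reported as `NA` with a warning while
$F'_{ST} = 1$ remains well defined.

$G'_{ST}$ uses Nei's multi-locus $G_{ST}$ (H_S and H_T averaged over loci,
population frequencies unweighted) and Hedrick's correction
$G'_{ST} = G_{ST}(s - 1 + H_S)/[(s-1)(1 - H_S)]$ with $s$ the number of
populations.

## Jackknife and classification

Confidence intervals come from the delete-one-population jackknife:
pseudovalues $\theta^*_i = n\hat\theta - (n-1)\hat\theta_{-i}$, centre =
mean pseudovalue, SE = sd/$\sqrt{n}$, CI = centre $\pm z\,$SE with
$z = 1.96$ (a t-quantile can be substituted), clamped to $[0,1]$ for
differentiation indices. For a linear statistic this is exact (the tests
assert the closed form for the mean to $10^{-12}$); for $F$ statistics its
95% intervals cover the generating value in 90–98% of simulation
replicates at the design scale. Delete-one subsets on which an estimator
fails (a region losing its last population) are skipped with a warning;
more than 20% failures aborts. Q and F' are jackknifed independently over
their own tables — the phenotype and genotype data may cover slightly
different population sets, as happens in real studies where some
populations are genotyped by proxy.

Significance is CI non-overlap, the most conservative reading available
when only estimates and intervals are published. Applied to the reference
study's printed intervals this rule reproduces all 14 diversifying /
unifying / neutral calls and all 7 between-level comparisons, which is the
strongest available evidence that it matches the original decision rule.

# The synthetic-data generator

Because the original field and garden data are unpublished, every stage is
exercised on generated data whose ground truth is known.

* **Phenotypes** follow the estimation model itself (Gaussian effects at
  each level, optional covariate slope and clipping effect), at the real
  design shape: 4 regions, 21 populations split 6/5/4/6, 6 families of 8
  plants, half of each family clipped. Default components
  $\sigma^2 = (2, 1, 1, 4)$ put roughly a quarter of the variance at the
  origin levels, a realistic heritability regime for morphological traits.
  The clipping effect defaults to $-2$ (clipping reduces trait values by
  about half a residual SD); the covariate is Gaussian (mean 3 cm, sd 1,
  floored at 0) with slope 0 by default so Q analyses are covariate-free
  unless requested.
* **Genotypes** come from a hierarchical Dirichlet model: ancestral
  frequencies per locus from a symmetric Dirichlet(1), region frequencies
  from a Dirichlet centred on them with concentration
  $c = (1-\theta_{RT})/\theta_{RT}$, population frequencies likewise with
  $\theta_{SR}$, then Hardy–Weinberg sampling of two copies per individual.
  The moment identity $E(F) = 1/(1+c)$ makes the targets checkable.
  Defaults — 5 loci, 8 alleles, 30 individuals per population,
  $\theta_{RT} = 0.1 \ll \theta_{SR} = 0.4$ — mirror a five-locus
  microsatellite panel with weak among-region but strong within-region
  drift, the regime the reference system shows.
* **Phenology** is multinomial per population from region-level stage
  probabilities; the default census gives the south-eastern region a
  late-flowering profile.

What the generator does *not* emulate: linkage, selfing (the species is
treated as fully outcrossing), mutation model (no stepwise structure in
allele codes), spatial autocorrelation within regions, genotype-by-
environment interaction, non-Gaussian trait errors. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to those violations — REML and the unweighted-means coefficients
are the components expected to matter most on messy real data.

# Numerical and testing choices

* Tolerances: oracle equivalences (brute-force AMOVA sums of squares,
  recode-and-recompute standardization, balanced EMS) are asserted to
  $10^{-10}$; the exact jackknife to $10^{-12}$; ANOVA–REML balanced
  agreement to $10^{-6}$ (optimizer-limited).
* Monte-Carlo problem sizes were chosen to keep the whole suite a
  few minutes long while leaving comfortable margins: 200 replicates for
  variance-component and Q recovery, 500 for jackknife coverage, 2000 for
  the G-test type-I rate, 20–100 random tables for the algebraic-property
  sweeps.
* Degenerate inputs fail loudly by design: constant traits (indices
  undefined), single-population regions (within-region component
  inestimable), monomorphic panels (no variation), expected-zero cells with
  observed counts. The one deliberate soft spot is the per-level `NA` for
  an unstandardizable $F'$ level, discussed above.
* Determinism: all generators take integer seeds; `runPipeline()` itself
  is RNG-free, and `writeResults()` output (CSV + JSON manifest, no
  timestamps) is byte-identical across reruns with identical inputs.

# Interfaces

The package is function-first: `simulateStudy()` → `runPipeline()` covers
the simulate / varcomp / qst / amova / jackknife / compare / correlate /
gtest workflow in two calls, with each stage also exported on its own, and
`scripts/acceptance.R` provides a seeded command-line entry point that
recomputes the headline numbers. Readers and writers speak plain CSV
(GenAlEx-style two-columns-per-locus genotypes, `NA` phenotype missing
marker, allele code 0 for missing copies). Coordinates are stored but never
consumed — elevation is the only geographic covariate used.

# Known limitations

* The unweighted-means EMS coefficients are an approximation under strong
  imbalance; REML is preferred there, and the two are compared on every
  balanced fixture.
* Jackknifing over populations treats regions as fixed: with only four
  regions the among-region components are estimated with few degrees of
  freedom and their intervals should be read accordingly.
* $F'_{RT}$ standardization at the region level follows this package's
  stated recoding convention; other software may differ at hierarchical
  levels.
* The CI non-overlap rule is conservative; nearly-touching intervals are
  called neutral.
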