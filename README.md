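# hierQF

Hierarchical Q–F comparison for common-garden phylogeography: did past
selection, or drift alone, shape trait differentiation among and within
phylogeographic regions?

## Who this is for

Evolutionary ecologists with (a) a common-garden phenotype table whose
plants are nested as region / population / seed family, and (b) codominant
microsatellite genotypes for the same (or overlapping) populations. The
package estimates hierarchical quantitative-trait differentiation
(`Q_RT` among regions, `Q_SR` among populations within regions), neutral
molecular differentiation by hierarchical AMOVA with standardized indices
(`F'_RT`, `F'_SR`, `F'_ST`, Hedrick's `G'_ST`), attaches
jackknife-over-populations 95% confidence intervals to everything, and
classifies each trait and level as under **diversifying** (`Q > F'`),
**unifying** (`Q < F'`) or no detectable selection (intervals overlap).
Trait–elevation correlations (Holm-corrected) and G tests on phenology
censuses cover the local-adaptation side. A design-matched synthetic-data
generator makes the whole pipeline testable without any external data.

## The statistics at the core

With nested variance components σ²_R (region), σ²_P (population), σ²_F
(seed family) and V_A = k·σ²_F (k = 4 for half-sib families, the default):

    Q_RT = σ²_R / (σ²_R + 2(σ²_P + V_A))        Q_SR = σ²_P / (σ²_P + 2 V_A)

Molecular counterparts come from a three-level AMOVA on allele-identity
distances (components a, b, c summed over loci):

    F_RT = a/(a+b+c)    F_SR = b/(b+c)    F_ST = (a+b)/(a+b+c)

each standardized by its maximum given within-population diversity
(allele recoding), and

    G'_ST = G_ST (s − 1 + H_S) / [(s − 1)(1 − H_S)].

Confidence intervals are delete-one-population jackknives
(pseudovalues θ*ᵢ = n·θ̂ − (n−1)·θ₋ᵢ, CI = centre ± 1.96·SE, clamped to
[0, 1]); significance is CI non-overlap.

## Worked example

```r
library(hierQF)
st  <- simulateStudy(seed = 7)                     # 4 regions / 21 pops / 6 fams / 8 plants
res <- runPipeline(st$phenotypes, st$genotypes, st$phenology)
res$selection_calls[, c("trait", "call_among_regions",
                        "call_within_regions", "level_comparison")]
#>       trait call_among_regions call_within_regions level_comparison
#> 1    height            neutral            unifying          greater
#> 2 leafRatio            neutral            unifying            equal
#> 3   biomass            neutral            unifying          greater
```

The generator planted strong regional variance in `height` and `biomass`
and mostly population-level variance in `leafRatio`; the calls read
accordingly: all three traits are less differentiated within regions than
the (strong, θ_SR = 0.4) neutral drift — unifying selection — and the two
region-heavy traits differentiate more among than within regions
(`greater`). The molecular side of the same run:

```r
res$molecular_indices
#>        index estimate lower upper
#> 1       F_RT   0.0789    NA    NA
#> 2       F_SR   0.3591    NA    NA
#> 3       F_ST   0.4097    NA    NA
#> 4 F_prime_RT   0.2920 0.134 0.470
#> 5 F_prime_SR   0.6751 0.610 0.739
#> 6 F_prime_ST   0.7702    NA    NA
#> 7       G_ST   0.3976    NA    NA
#> 8 G_prime_ST   0.7536    NA    NA
```

Raw `F_RT`/`F_SR` land close to their generating targets (0.1 / 0.4); the
standardized indices are larger, as they must be.

As a published-data worked example, `campanulaIndices()` ships the printed
Q/F' estimates and intervals of an Alpine *Campanula thyrsoides*
common-garden study; `selectionCalls()` on those intervals reproduces all
14 published selection calls and all 7 among- vs within-region
comparisons, e.g. maximum inflorescence height
`Q_RT 0.371 (0.355–0.387)` against `F'_RT 0.092 (0.080–0.105)` →
diversifying.

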