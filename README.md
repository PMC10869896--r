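# fniche

Intraspecific functional-niche analysis in trait space, packaged for the
kind of study where one species is sampled on fixed transects, split into
biologically meaningful groups (here: juveniles, males, females), measured
morphometrically, and related to the microhabitat of the transects where
the individuals were caught.  It is aimed at ecologists who want the whole
chain — trait construction, functional space, niche metrics, habitat
models, trait–environment ordination — as tested, seed-reproducible
functions rather than a script pile.

## What it computes

Raw measurements (mass `M` plus ten linear measurements) become nine
unitless functional traits (`log10(M+1)`, `IO/HW`, `MW/HW`,
`(HW·HL·HH)^{1/3}`, `FLL/SVL`, `HLL/SVL`, `FLL/HLL`, `TAL/SVL`,
`AMW/SVL`), which are z-scored and eigendecomposed; axes with eigenvalue
> 1 span the functional space. In that space, for groups *A*, *B* with
convex hulls `H(A)`, `H(B)`:

- **FIde(A)** = abundance-weighted mean position of *A* (centroid),
- **FRic(A)** = `100 · V(H(A)) / V(H(pooled))` — richness as a share of
  the population's occupied trait space,
- **FOve(A,B)** = `V(H(A) ∩ H(B)) / (V(H(A)) + V(H(B)) − V(H(A) ∩ H(B)))`
  — Jaccard overlap of hull hypervolumes,

with subsample-bootstrap 95% confidence intervals and a one-way PERMANOVA
(pseudo-F on Euclidean distances, permutation p with the +1 convention).
Hull and hull-intersection volumes are exact, computed in compiled code by
facet enumeration and simplex-pair clipping (dimensions 2–6), not by
Monte-Carlo — Monte-Carlo rejection sampling serves only as an oracle in
the tests.

Per-group transect counts are modelled with all-subsets log-link GLMs
ranked by AICc (`−2·logL + 2k + 2k(k+1)/(n−k−1)`), after Shapiro–Wilk
normality screening and Spearman/Pearson collinearity screening
(`|r| ≥ 0.9` pairs collapsed); a best model is declared only at ΔAICc > 2,
otherwise Akaike-weight model averaging with unconditional standard errors
is reported, plus Chevan–Sutherland hierarchical partitioning of each
predictor's independent contribution.  Trait–environment coupling is
assessed by redundancy analysis gated on a DCA gradient length < 3 SD,
with 999-permutation significance tests overall and per variable.

A calibrated synthetic generator (`simulate_dataset()`) reproduces the
statistical structure this design assumes — 11 transects, groups of
40/30/41, separated trait centroids, a 0.958 temperature correlation and a
−0.907 ground-cover correlation, Poisson counts on a log-linear habitat
preference — so the entire pipeline runs and is tested without any field
data.

## Worked example

```r
library(fniche)

dat <- simulate_dataset(simulation_config(seed = 42))
tm  <- standardize_traits(compute_traits(dat$individuals))
fs  <- build_space(tm)
fs
#> Functional space: 4 retained axes (eigenvalue > 1) of 9
#>   PC1: eigenvalue 2.356, 26.18% of variance
#>   PC2: eigenvalue 1.969, 21.88% of variance
#>   PC3: eigenvalue 1.619, 17.99% of variance
#>   PC4: eigenvalue 1.175, 13.05% of variance

nm <- niche_metrics(fs, n_perm = 999, seed = 1)
round(nm$fric, 2)
#>   female juvenile     male
#>    45.18    31.74    24.59
nm$permanova$p
#> [1] 0.001
```

Four axes carry 79% of the trait variance.  Functional richness says each
group occupies 25–45% of the population's trait space, and the PERMANOVA
p-value (0.001 is the smallest attainable at 999 permutations) confirms
the groups sit at different positions in that space — the generator builds
in a 2-SD centroid separation, and the pipeline recovers it.  Habitat
models and the RDA follow the same pattern:

```r
res <- run_pipeline(pipeline_config(dat$individuals, dat$transects,
                                    seed = 1, n_boot = 2000,
                                    n_boot_fove = 200, n_perm = 999))
res$habitat$male$partition      # independent contributions, % of total
res$ordination$dca              # gradient length -> RDA vs CCA
res$ordination$rda              # canonical axes, % variance, perm test
```

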