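---
title: "Quantifying intraspecific functional niches: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intraspecific functional niches: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fniche)
```

`fniche` implements a complete trait-based workflow for asking how much the
functional niche varies *within* a species — here phrased for a plateau
lizard study design in which juveniles, males and females are captured on
fixed transects, measured morphometrically, and related to the microhabitat
of the transects where they were found.  This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic data
generator does and does not emulate.

## From morphometrics to functional traits

Each individual carries body mass `M` (g) and ten linear measurements (mm).
`compute_traits()` converts them into nine unitless functional traits:
`Mass = log10(M + 1)`, eye position `EP = IO/HW`, mouth shape `MS = MW/HW`,
head size `HS = (HW*HL*HH)^(1/3)`, relative fore- and hindlimb lengths
`RFL = FLL/SVL`, `RHL = HLL/SVL`, limb ratio `LR = FLL/HLL`, relative tail
length `RTL = TAL/SVL` and relative abdominal width `RAW = AMW/SVL`.  The
ratios remove overall body size; `Mass` and `HS` deliberately keep it,
because absolute size and bite performance are themselves ecologically
meaningful.  Two conventions had to be fixed where usage in the literature
varies: the logarithm's base (base 10, the morphometric convention;
configurable via `log_base`) and the head-size formula (the cube root of
the head-dimension product, so `HS` stays on a length scale; the raw
product would have units mm^3 and dominate any variance-based analysis).
`standardize_traits()` z-scores each trait with the sample (n − 1) standard
deviation; the centring constants are stored so the transformation is
invertible to 1e-10 (`unstandardize_traits()`).

## The functional space

`build_space()` eigendecomposes the trait correlation matrix and retains
every axis with eigenvalue above 1 (Kaiser criterion, with a `1e-12` guard
so a tie at exactly 1 is kept, since the retention decision should not
depend on the last floating-point bit).  Individual scores on the retained
axes are the functional space; trait–axis Pearson correlations (which for
correlation PCA equal eigenvector times the square root of the eigenvalue)
describe what each axis means.  PCA signs are arbitrary, so each axis is
oriented to make its dominant trait load positively — results are
reproducible across BLAS implementations up to this convention, which the
tests enforce by comparing against `prcomp()` only up to sign.

## Convex-hull niche metrics

Three indices summarize each group's niche in the retained space:

* **FIde** (functional identity): the abundance-weighted mean position,
  with unit weights by default so each captured individual counts once.
* **FRic** (functional richness): the convex-hull volume of the group's
  points, expressed as a percentage of the convex-hull volume of *all*
  individuals pooled.  The denominator makes group richness a share of the
  population's occupied trait space; an absolute-volume reading is
  available through `hull_volume()` directly.
* **FOve** (functional overlap): for a pair of groups, the volume of the
  intersection of their hulls divided by the volume of their union
  (inclusion–exclusion) — a Jaccard index on hypervolumes, in [0, 1].

The geometry is computed exactly, in compiled code, without an external
geometry library: facets are found by exhaustive supporting-hyperplane
enumeration over point d-subsets, volumes by fan triangulation (with
non-simplicial facets triangulated recursively after an isometric
projection), and intersection volumes by triangulating *both* hulls and
summing simplex–simplex intersection volumes, each obtained by vertex
enumeration over the at most `2(d + 1)` pooled facet half-spaces of a
simplex pair.  This design was chosen over clipping one hull's simplices
by all of the other hull's half-spaces because the pairwise decomposition
bounds the constraint count per cell, avoiding combinatorial blow-up, and
it makes `FOve(A, A) = 1` hold exactly (a hull intersected with itself
reproduces its own triangulation).  The test suite checks the geometry
against analytic polytopes and a 10^6-sample Monte-Carlo rejection oracle;
the Monte-Carlo route is deliberately kept as an oracle only.  Tolerances
are relative (`1e-9` of the bounding-box diagonal) throughout; degenerate
inputs (fewer than d + 1 points, affinely dependent sets) have volume 0 by
convention, and FOve is an error in that case rather than silently 0.
Dimensions 2–6 are supported, comfortably covering eigenvalue>1 retention
on nine traits.

Sampling effort affects hull volumes, so observed FRic/FOve are
complemented by a subsample bootstrap (`bootstrap_metric()`): draw a fixed
number of individuals per group *without replacement* (the reading of
"randomly selecting n individuals" adopted here; with-replacement is
available via `replace = TRUE`), recompute the metric, and report the
2.5th/97.5th percentile interval over replicates.  Groups at or below the
subsample size cannot be strictly subsampled and are skipped with a notice
— their entries are reported as missing, matching the dashes field studies
print for the minimum-size group.  The resampling is restricted to the
focal group(s); the pooled-hull denominator stays fixed, so the intervals
isolate sampling noise in the group hull rather than in the reference
space.

Group position differences are tested with a one-way PERMANOVA
(`permanova()`) on Euclidean distances among the retained-axis scores —
the space in which the hull metrics live; a variant on the nine
standardized traits gives the same pseudo-F up to the discarded axes'
variance and can be run by passing the trait matrix as coordinates.  The
permutation p-value uses the `(1 + exceedances)/(1 + n_perm)` convention,
so it is never exactly zero and its smallest attainable value at 999
permutations is 0.001.

## Habitat models

Per-transect capture counts of each group are modelled against the
transect's microhabitat.  The variable screening mirrors standard
practice: Shapiro–Wilk normality per variable, then pairwise correlations
— Spearman when either member is non-normal, Pearson otherwise — with
pairs at `|r| >= 0.9` and `p < 0.05` collapsed to one member.  Which
member survives is governed by `prefer` (defaults: soil temperature over
surface ground temperature, clumping-grass over bare-soil coverage, the
ecologically more proximate variables).  Chained collinearity is resolved
greedily in decreasing `|r|`.

`all_subsets()` fits every predictor subset as a log-link count GLM
(Poisson by default; negative binomial via `family = "negbin"` when
counts are overdispersed — the package surfaces the choice rather than
automating it, since 11 transects give little power to diagnose
dispersion) and ranks models by AICc,
`-2 logLik + 2k + 2k(k + 1)/(n - k - 1)`.  Predictors are z-scored before
fitting so coefficients are comparable across variables and subsets.  A
best model is declared only when the runner-up is more than 2 AICc units
away; otherwise the table is flagged ambiguous and `model_average()` is
the recommended summary: full (zero-substitution) averaging with Akaike
weights and Burnham–Anderson unconditional standard errors
`sum_i w_i sqrt(se_i^2 + (beta_i - beta_bar)^2)`.  At very small n, model
rows whose AICc is undefined (`n <= k + 1`) or whose fit fails are
retained in the table but flagged and excluded from the weights.

`hierarchical_partition()` decomposes the full model's goodness of fit
(deviance-explained for count GLMs, R^2 for Gaussian) into per-predictor
independent contributions by Chevan–Sutherland averaging over all model
hierarchies.  Two properties anchor the implementation and are tested: the
independent contributions sum exactly to the full-model goodness of fit,
and with exactly orthogonal predictors each `I_j` equals the predictor's
marginal fit (joint contributions `J_j = R({j}) - I_j` then vanish).  For
the near-saturated subsets that arise with ~10 predictors on 11 transects
the enumeration uses a permissive fitting mode (`strict = FALSE`:
saturated fits allowed, non-convergence after 100 IRLS iterations
tolerated), the behaviour classic hierarchical-partitioning software
exhibits; ranked model selection keeps the strict rules.

`run_pipeline()` additionally protects the study-scale regime: when the
screen leaves more candidate predictors than the transects can support
(more than `n - 2`), the per-group candidate set is capped at the
variables most rank-associated with that group's counts, and the RDA
constraint set is capped at one less than the number of occupied
transects (environment values repeat within a transect, which bounds the
rank of the individual-level matrix).  Both caps announce themselves with
messages.

Aspect is treated as a plain linear covariate in degrees.  This follows
the field protocol the package mirrors, and is documented here because it
is statistically questionable for a circular variable; a sine/cosine
decomposition is a natural user-side extension.

## Trait–environment ordination

Whether a linear or unimodal response model is appropriate is decided by
a detrended correspondence analysis gate (`dca_gradient_length()`, via
`vegan::decorana`, detrending by 26 segments): an axis-1 gradient shorter
than 3 SD of turnover recommends RDA, longer recommends CCA.
Correspondence analysis needs nonnegative input while standardized traits
are centred, so each column is min-shifted to zero first — the least
intrusive nonnegativity transform, but worth stating since the gate's
length is not invariant to it.  A matrix with identical rows collapses to
zero under the shift; it has no gradient, and length 0 / RDA is returned
directly.  CCA itself is intentionally not implemented
(`cca_traits_env()` says so): short trait gradients are the regime this
package targets.

`rda_traits_env()` is redundancy analysis from first principles:
multivariate least squares of the standardized traits on the (z-scored)
environment of each individual — each lizard carries its transect's
microhabitat values, so the ordination lives at the individual level, with
the transect-mean alternative available by aggregating before the call —
followed by an eigendecomposition of the fitted values.  Canonical
eigenvalues are reported as percentages of total trait variance;
constrained plus residual variance reconstructs the total to 1e-8 (tested,
along with the identity that constraining on the traits' own principal
components returns the PCA spectrum, and agreement with `vegan::rda`).
Trait and environment arrows are correlations with the axis scores
("type 2" scaling), so the cosine between two arrows approximates the
correlation between the variables.  Significance uses a permutation test
(`rda_permutation_test()`, default 999 permutations) of the pseudo-F
`(constrained/q) / (residual/(n - q - 1))` under row permutation of the
environment, and `rda_term_significance()` runs the same test per variable
to select the arrows worth drawing (marginal tests at `p < 0.05`; a full
forward-selection path adds little at q <= 9 and is left out).

## The synthetic study generator

`simulate_dataset()` exists so every stage above is testable with no
field data.  Its defaults *are* the study conditions the pipeline
targets: 11 transects; 40 juveniles, 30 males, 41 females; juveniles
defined by snout-vent length under 40 mm; group trait centroids separated
by 2 within-group SDs along fixed contrasts (juveniles lighter and
smaller-headed with relatively longer limbs and tails; females heavier
with wider abdomens; males intermediate); surface-ground and soil
temperature correlated at 0.958; bare-soil and clumping-grass coverage
correlated at -0.907 on the logit scale (coverages are simulated on the
logit scale and mapped to percent so the [0, 100] bounds are respected
while preserving the negative association); counts Poisson with log-link
coefficients on z-scored environments encoding the qualitative habitat
preferences the models should recover (juveniles toward warm, rocky, dry
transects; males and females away from high illuminance; males away from
dense clumping grass).  Individuals are allocated to transects with
probability proportional to their group's expected count — a Poisson
count model conditioned on the group total — so the individual and
transect tables agree exactly.

Individuals are simulated on the *latent trait scale* and back-transformed
through the trait formulas (inverted where needed) to raw morphometrics.
This guarantees two properties the tests rely on: the group structure is
exactly where the analysis looks for it (trait space), and at
`trait_centroid_shift = 0` the groups' trait distributions are exchangeable,
so downstream group-difference tests must reject at their nominal rate.
Within-group trait correlations follow four latent factors (size, head
shape, limbs, with tail length joining the limb factor and abdominal width
the size factor); together with the contrast separation this yields a
pooled correlation spectrum whose first four eigenvalues exceed 1 with a
clear gap (≈ 2.2, 2.0, 1.6, 1.25, then ≤ 0.7 at the default size) — the
four-axis retention regime the analysis is designed around, chosen once to
match what real lizard trait sets show.  Per-group trait means and SDs are
not published quantities; the defaults were picked for qualitative realism
and are not calibrated to reproduce any printed value.

What the generator does *not* emulate: measurement error on the calipers,
allometric coupling between juveniles' raw head/mass values and body
length (trait-level exchangeability at zero shift was prioritised over
raw-scale allometry), spatial structure among transects, repeat-capture
dynamics, and any direct trait–environment coupling beyond what group
composition induces.  Passing tests therefore demonstrate the statistical
machinery, not that real lizards behave this way.

## Problem sizes, determinism, and runtime

Exact hull intersections are the expensive primitive (order 0.1–0.5 s for
two ~40-point hulls in four dimensions); single-hull volumes are
milliseconds.  The pipeline therefore separates `n_boot` (FRic replicates,
default 10000 as in the field protocol) from `n_boot_fove`, and the
package's own reproducibility script runs the pipeline at 2000 FRic and
200 FOve replicates with 999 permutations — interval endpoints then carry
Monte-Carlo noise of a few tenths of a percentage point, which is the
resolution at which its outputs should be read.  The test suite uses
smaller replicate counts still, sized so each statistical property is
checked at ±3 Monte-Carlo standard errors.  All stochastic stages accept
seeds; `run_pipeline()` derives a per-stage child seed from one global
seed, so stage results are reproducible independently of execution order.

## Known limitations

Convex hulls are sensitive to outlying individuals (no kernel-density
hypervolume alternative is provided); FOve is pairwise only; the
collinearity screen is greedy rather than optimal; aspect's circularity is
ignored by design; and the DCA gate inherits `decorana`'s detrending
conventions.  At 11 transects the habitat models are deliberately
reported with model-averaged uncertainty rather than a single best model
unless the AICc gap exceeds 2.
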