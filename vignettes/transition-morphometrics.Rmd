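---
title: "Quantifying morphological transitions: methods behind morphorates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphological transitions: methods behind morphorates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphorates)
```

# Overview

`morphorates` implements a complete workflow for asking how a major
ecological transition — the motivating case is the land-to-water transition
in carnivorans, where pinnipeds (seals, sea lions, walruses) evolved from
terrestrial ancestors — reshapes morphological diversity. The workflow runs
from raw 3D landmark coordinates to phylogenetic model comparison:

1. **Morphometry** — mirror-filling of one-sided missing landmarks,
   generalized Procrustes analysis (GPA), extraction of the symmetric shape
   component, species means, and tangent-space principal component analysis
   (PCA).
2. **Disparity** — sum of ranges and mean distance to centroid per
   ecological group, with bootstrap confidence intervals and rarefaction.
3. **Evolutionary models** — maximum-likelihood Brownian motion (BM) and
   multi-optima Ornstein–Uhlenbeck (OU) fits over painted regime
   hypotheses, compared by AIC.
4. **Branch rates** — the Independent Evolution (IE) estimator of ancestral
   states and branch-specific rates, with time-sliced morphospace export.
5. **Synthetic data** — a generator producing trees, trait histories and
   landmark datasets with known ground truth, so every stage is testable
   without access permissions to museum specimens.

Every result type is a tibble (or carries tibble methods via `tidy()`,
`glance()`, and `as_tibble()`) and has an `autoplot()` method.

# Morphometry

## Mirror-filling missing landmarks

Museum specimens are frequently damaged on one side. When a landmark scheme
has bilateral symmetry, a missing landmark can be recovered by reflecting
its preserved antimere across the specimen's symmetry plane. `mirror_fill()`
estimates that plane by total least squares through the midline landmarks:
the plane normal is the right singular vector of the centred midline
coordinates with the smallest singular value. The missing partner is then
the Householder reflection of the preserved one. Requirements and failure
modes:

* At least three non-collinear midline landmarks must be present
  (collinearity is detected from the ratio of the two smallest singular
  values); otherwise the specimen is flagged *unfillable* rather than
  silently imputed.
* If both members of a pair are missing, they stay missing and a warning is
  emitted.

## Generalized Procrustes analysis

`gpa()` removes position, scale, and orientation: configurations are
centred, scaled to unit centroid size, and rotated to a consensus by
singular value decomposition, iterating until the consensus changes by less
than `1e-10` (default cap 200 iterations). Rotations are proper
(determinant +1); for effectively planar configurations a proper 3D rotation
can still realize an in-plane reflection, which is the expected behaviour
of rotation-only superimposition in three dimensions. `procrustes_distance()`
is the root-sum-of-squares distance after optimal superimposition of one
configuration onto another.

## Symmetric shape component

For landmark schemes with object symmetry, the biologically meaningful
signal is usually the symmetric component of shape; the asymmetric
remainder mixes fluctuating asymmetry with measurement error.
`symmetrize()` averages each aligned configuration with its relabelled
reflection and re-runs the superimposition. Because reflection and
re-alignment interact, this is iterated to a fixed point (tolerance
`1e-12`), which makes `symmetrize()` exactly idempotent — a property the
test suite checks directly. `asymmetry_scores()` reports the distance of
each specimen from its own symmetric component, which is also a practical
screen for digitizing errors.

## Tangent-space PCA

Shapes live on a curved manifold; statistics are done in the linear tangent
space at the mean. `tangent_pca()` centres the species-mean configurations
on the consensus, projects out the component along the consensus direction
(the standard orthogonal tangent projection), and performs PCA on the
result. Properties maintained by construction and enforced by tests:

* percent variance sums to exactly 100;
* scores are an isometric embedding — Euclidean distances among scores
  equal distances among projected configurations;
* loadings are orthonormal, and `center + scores %*% loadings` reconstructs
  the projected coordinates to numerical precision;
* each axis has a deterministic sign convention (the loading of largest
  magnitude is positive), so runs are reproducible across platforms.

# Disparity

Two complementary metrics are provided. The **sum of ranges** is
sensitive to sample size (ranges only grow as specimens are added), so
group comparisons use **rarefaction**: the metric is averaged over
bootstrap subsamples of a fixed size `m` drawn with replacement. The
**mean distance to centroid** is a variance-style metric, much less
sample-size sensitive, and is reported with percentile bootstrap
confidence intervals (at least 100 replicates enforced).
`disparity_table()` assembles both per group; fossil species are excluded
from disparity (their sampling is not comparable) while remaining in the
ordination and the model-fitting stages, controlled by a per-species flag.

# Evolutionary models

Species scores on the leading PCs are modelled on a time-calibrated
phylogeny. Under **BM**, the trait covariance between two species is
proportional to their shared path length, and the likelihood is a
multivariate normal evaluated with a Cholesky-based generalized
least-squares root estimate; the rate estimate is the standard
maximum-likelihood `sigma2 = q/n`.

Under the **multi-optima OU (Hansen) model**,

$$dX(t) = \alpha\,[\theta(t) - X(t)]\,dt + \sigma\,dB(t),$$

each branch carries a regime with its own optimum `theta`; `alpha` sets
how quickly lineages are pulled toward the current optimum. The expected
tip value is the exponentially weighted average of the optima along its
root-to-tip path (Hansen weights), and for possibly non-ultrametric trees
the covariance between tips `i` and `j` with divergence depth `d_a` is

$$V_{ij} = \frac{1}{2\alpha} e^{-\alpha (d_i + d_j - 2 d_a)}
  \left(1 - e^{-2\alpha d_a}\right).$$

`fit_ou()` profiles `theta` (GLS) and `sigma2` analytically at fixed
`alpha`, and maximizes over `alpha` on a logarithmic grid spanning
`1e-8` to `50 / tree height`, refined by `optimize()` in the best grid
cell. As `alpha -> 0` the OU likelihood converges to BM; the
implementation reproduces the BM log-likelihood to within `1e-4` at
`alpha = 1e-6`, which the tests verify. Parameter counts for AIC are
`2m` for BM and `m (2 + R)` for an `m`-trait, `R`-regime OU model.

## Regime paintings

`paint_regimes()` encodes four hypotheses about a focal "aquatic" clade
and an optional convergent ("otter-like") terminal:

* `BM` — no regimes (pure drift);
* `one_regime` — a single global optimum;
* `terrestrial_aquatic` — the focal clade's stem and crown plus the
  convergent terminal share a shifted optimum;
* `pinniped_radiation` — a shift confined to a sub-radiation.

`compare_models()` fits all hypotheses on one or more topology variants
(analyses of this kind are often run on alternative published topologies)
and reports log-likelihood, parameter count, AIC and delta-AIC per row.

A caution from our own validation experiments: when the generating process
is BM, a shift hypothesis gains spurious log-likelihood on small trees
because the shifted optimum is unidentified as `alpha -> 0` (a boundary
non-identifiability of the Davies type). On trees of a few dozen tips
these spurious gains commonly reach 2–3.5 log-units; they shrink with
tree size. Model-selection simulations in this package therefore run at
150 tips, and users should treat small-tree AIC differences of this
magnitude with suspicion.

# Independent Evolution rates

The IE estimator assigns a rate to every branch rather than one rate per
regime. It proceeds in two steps at each internal node:

1. **Gradual expectation** — maximum-likelihood BM ancestral states: the
   unique minimizer of the sum over branches of squared change divided by
   branch length (a sparse weighted least-squares solve).
2. **Barycentre triangulation** — the node value is re-estimated as the
   inverse-branch-length-weighted barycentre of the ancestor's expectation
   and the two descendant values. The branch rate is the distance from the
   barycentre to the descendant, optionally divided by branch length
   (`rate_per_my`); `multivariate_branch_distance()` combines traits into a
   per-branch Euclidean displacement.

Because the barycentre is pulled toward the descendants, IE *shrinks*
single-branch bursts: in our validation a burst simulated at 10x the
background rate is recovered at roughly half its true magnitude, yet still
ranks in the upper tail. On birth-process trees, extremely short terminal
branches dominate the *time-standardized* rate tail (dividing a noisy
displacement by a tiny branch length), so burst-detection validation uses a
balanced tree with equal branch lengths, where ranking is driven by
displacement alone. Users ranking `rate_per_my` on real trees should
inspect the branch lengths of their top candidates.

`morphospace_frames()` exports, for a grid of time slices, the
interpolated position of every lineage alive at that time in chosen PC
axes — the data behind "evolution of the morphospace" animations. Age
comparisons use a tolerance relative to tree height, because path-length
sums in grafted or rescaled trees carry rounding noise proportional to
their magnitude.

# The synthetic generator

`simulation_spec()` + `simulate_dataset()` produce a full study in
miniature. Design choices aimed at realism:

* **Trees** are constant-rate birth simulations, optionally rescaled to a
  fixed height (default scenarios use 60 units, a carnivoran-like
  timescale), with optional fossil tips grafted at a stated divergence
  and tip age.
* **Traits** evolve by exact transition sampling: each branch draws from
  the exact BM or OU transition distribution (using `expm1` for numerical
  stability at small `alpha x t`; `alpha = 0` falls back to BM), so no
  time-discretization error enters. Regime paintings switch parameters
  mid-lineage.
* **Landmarks** are built from a skull-like template (three midline
  points, four bilateral pairs) by perturbing it along `p` orthonormal
  basis directions scaled by the trait values, then adding per-specimen
  digitizing noise, random similarity transforms (nuisance position,
  orientation, scale), and optionally whole-side missingness — precisely
  the pathologies the morphometric stack must undo. Because the basis is
  orthonormal and symmetric, trait geometry is recoverable from the
  landmarks up to the nuisance transforms.
* **Ground truth** (`synthetic_truth`) records node states, per-branch
  displacement and regimes, so recovery can be scored exactly.
* **Seeding** — every stochastic stage (tree, traits, landmarks,
  missingness, bootstrap, rarefaction) draws its seed from a named
  substream of the master seed, so changing the specimen noise cannot
  perturb the tree.

`make_demo()` packages a two-clade scenario — a large old clade at the
ancestral optimum, a smaller young nested clade at a shifted optimum, one
convergent terminal, one fossil tip — sized to run in well under a minute.

# Reproducibility

Every table written by `run_pipeline()` carries a provenance header with
the seed, a configuration hash, and the producing stage, and identical
configurations produce byte-identical outputs. Non-convergent fits and
unfillable specimens are logged, not silently dropped. Partial failures
abort with stage-named errors.

# Limitations

* The OU machinery fits *fixed* (user-painted) regime hypotheses; it does
  not search for the number or placement of shifts.
* Traits are fitted independently (no evolutionary covariance between PC
  axes), the standard simplification for score-based analyses.
* IE rates are shrunken estimates of branch-specific change, best used for
  ranking rather than as absolute rates.
* The mirror-filling model assumes perfect object symmetry of the template;
  directional asymmetry will bias filled landmarks.
* Disparity rarefaction resamples with replacement, so rarefied values at
  `m = n` still sit slightly below the full-sample sum of ranges.

# References

* Gower, J.C. (1975) Generalized Procrustes analysis. *Psychometrika* 40.
* Rohlf, F.J. & Slice, D. (1990) Extensions of the Procrustes method for
  the optimal superimposition of landmarks. *Systematic Zoology* 39.
* Klingenberg, C.P., Barluenga, M. & Meyer, A. (2002) Shape analysis of
  symmetric structures. *Evolution* 56.
* Foote, M. (1991) Morphological and taxonomic diversity in a clade's
  history. *Contributions from the Museum of Paleontology* 28.
* Hansen, T.F. (1997) Stabilizing selection and the comparative analysis
  of adaptation. *Evolution* 51.
* Butler, M.A. & King, A.A. (2004) Phylogenetic comparative analysis: a
  modeling approach for adaptive evolution. *The American Naturalist* 164.
* Smaers, J.B. & Vinicius, L. (2009) Inferring macro-evolutionary events
  based on data from extant taxa: the Independent Evolution method.
  *Journal of Human Evolution* 57 (the IE estimator).
* Jones, K.E., Smaers, J.B. & Goswami, A. (2015) Impact of the terrestrial–
  aquatic transition on disparity and rates of evolution in the carnivoran
  skull. *BMC Evolutionary Biology* 15.
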