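---
title: "Models and methods behind elevdisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind elevdisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevdisp)
```

`elevdisp` quantifies how phylogenetic relatedness and functional traits
structure presence/absence communities sampled along elevational
transects, and decomposes that structure into environmental, spatial and
phylogenetic components. This vignette is the package's own account of
the statistical machinery: what each piece assumes, which knobs matter,
and where we made judgement calls.

## Data model

Four objects describe a study. A rooted phylogeny with branch lengths
(Newick; need not be ultrametric — every formula below is defined for
general branch lengths). A sites × species occurrence matrix with a
transect id per site; counts are accepted but are immediately reduced to
presence/absence, because surveys pooled from heterogeneous sources do
not carry comparable abundances. A species × traits table mixing
continuous and binary traits (columns whose values are all 0/1 are
flagged binary unless overridden). A site table with elevation (m),
geographic coordinates (decimal degrees) and environmental covariates.

Identifiers are matched case-sensitively after trimming surrounding
whitespace: silent case-folding hides data errors. Species that occur in
the community but lack a tree placement (a common situation when no
sequence data exist for a species) are, under the default
`drop_with_warning` policy, removed from tree-based analyses only — they
remain in every trait-based computation — and every such decision is
returned in a machine-readable report. Tree tips absent from the
community are pruned; pruning never changes cophenetic distances among
the remaining tips, which the test suite verifies.

## Range interpolation

Sampling along a mountainside is sparse, so a species recorded at 1000 m
and 2000 m on one transect but missed at an intermediate site very
likely occurs there. Within each transect independently, every site
whose elevation lies *strictly between* a species' lowest and highest
occupied elevations is filled in; occurrences are never removed, the
operation is idempotent, and it never crosses transect boundaries.
Strict betweenness is evaluated on the numeric elevation, not on site
rank, so unevenly spaced and tied elevations behave sensibly: a site at
an elevation equal to an interior occupied site is filled, while a site
at exactly the range endpoint is treated as the endpoint itself.

## Dispersion and the independent-swap null

Community structure is measured per site by the mean pairwise distance
among co-occurring species (MPD, sensitive to deep, "basal" structure)
and the mean nearest-taxon distance (MNTD, sensitive to "terminal"
structure), on one of three distance bases:

* phylogenetic: cophenetic (path-length) distances on the tree;
* single trait: absolute difference after standardizing the trait to
  zero mean and unit variance over the species pool (binary traits use
  the 0/1 mismatch);
* all traits: Gower distance — range-normalized absolute differences for
  continuous traits, mismatches for binary ones, averaged over traits.

The literature rarely states its single-trait distance; the
standardized absolute difference used here is the simplest choice that
makes traits with different units comparable, and the choice is
documented rather than hidden (see Open choices below).

Observed values mean little without a null. The package uses the
independent-swap randomization: a Markov chain whose moves exchange
2×2 checkerboard submatrices, preserving every site's richness and every
species' prevalence exactly. The chain is symmetric, hence its
stationary distribution is uniform over the fixed-margin matrix set; on
a 4×4 example the test suite checks, by exhaustive enumeration, that all
90 fixed-margin matrices are visited with uniform frequency. The default
schedule — burn-in of 10,000 attempted swaps, 1,000 attempts between
each of 999 draws — mixes comfortably at the matrix sizes this package
targets (tens of sites × tens of species); both knobs are exposed.

For each site, `SES = (mean_obs − mean_null) / sd_null`; positive values
indicate overdispersion, negative values clustering. Sites with fewer
than two species, or whose null distribution is degenerate
(`sd_null = 0`, e.g. a species set frozen by the margins), are flagged
undefined and excluded from downstream regressions rather than silently
zeroed. A self-calibration property anchors the scale: on communities
generated by the null itself, SES across 200 sites has mean ≈ 0 and
standard deviation ≈ 1 (checked in the test suite).

The species pool is the whole dataset, not the transect: this matches
the convention of the picante tradition the field uses, and the
alternative would shrink margins to near-degeneracy on 5-site transects.

## Phylogenetic signal

**Blomberg's K** (continuous traits) compares the trait's variance
around the GLS ancestral mean with the phylogenetically corrected mean
square, scaled by the Brownian-motion expectation computed from the tree
alone:

K = (MSE0 / MSE) / [(tr(V) − n / (1'V⁻¹1)) / (n − 1)],

with V the phylogenetic covariance matrix (shared root-to-MRCA branch
lengths). K = 1 under Brownian motion; on an equal-branch star tree
(V ∝ I) K equals 1 exactly for *every* trait vector, which the suite
asserts to 1e-10. Significance comes from tip-label permutation of K
itself — not of the PIC variance as some implementations do — so the
reported p-value refers to the reported statistic; this is a documented
divergence from, e.g., `picante::phylosignal`, while the K value itself
matches `picante::Kcalc` to 1e-10 in cross-checks.

**Fritz–Purvis D** (binary traits) measures the total amount of state
change Σd implied by post-order nodal averaging (each internal node's
value is the mean of its children's — the natural generalization to the
polytomies that consensus trees contain), scaled between two reference
points computed on the same tree at the observed prevalence:

D = (Σd_obs − mean Σd_Brownian) / (mean Σd_random − mean Σd_Brownian).

D ≈ 1 for phylogenetically random states and D ≈ 0 (or below) for
Brownian-threshold-clumped states; both calibrations are verified on
64-tip trees. Brownian-threshold simulations use σ² = 1, which is
irrelevant to D's value because thresholding at a quantile is
scale-free. Two p-values are always reported — the permutation
probability of as little change as observed (`p_random`) and the
Brownian-simulation probability of as much change as observed
(`p_brownian`) — because published tables often leave ambiguous which
one accompanies a D value. Both use the (1 + count)/(n + 1) estimator so
they are never exactly zero. If the two reference means coincide
(possible on very small trees where every arrangement at prevalence k/n
is equivalent) the statistic is refused with a diagnostic rather than
returned as a division by noise.

## Space: combined distance and PCNM eigenvectors

In steep terrain, map distance understates ecological separation; the
spatial distance is therefore the great-circle (haversine) distance on a
sphere of radius 6,371,000 m *plus* the absolute elevational difference,
both in metres. A spherical Earth is used rather than a projection
because study regions spanning >10° of latitude have no single
appropriate plane.

The distance matrix is converted to spatial predictors by the canonical
PCNM recipe: truncation at the longest minimum-spanning-tree edge t
(the smallest threshold keeping the neighbourhood graph connected),
replacement of larger distances by 4t, Gower double-centring of
−d*²/2, eigendecomposition, and retention of axes with eigenvalue
above max(eigenvalue) × 1e-9, each scaled by the square root of its
eigenvalue. On equally spaced sites along a line the leading axes are
the expected sinusoid-like waves with 1, 2, 3 sign changes. Eigenvector
sign is arbitrary, so each axis's largest-magnitude entry is forced
positive — without a convention, rerunning an analysis could flip
regression coefficients. All positive-eigenvalue axes are kept
(negative-autocorrelation axes are out of scope); which axes *matter* is
delegated to forward selection. The implementation agrees with
`vegan::pcnm` to 1e-10 in eigenvalues and up to sign in eigenvectors.

## Explaining dispersion: selection and variance partitioning

Each SES response is regressed on three predictor sets: environment
(the site covariates), space (PCNM axes) and phylogeny (the site's
SES.MPD and SES.MNTD on the phylogenetic basis — the standard design in
which phylogenetic dispersion is itself a candidate explanation of trait
dispersion).

Forward selection uses the double stopping criterion: the global model
(all candidates) must first pass a permutation F-test at α; candidates
then enter by largest R² improvement, each tested by a Freedman–Lane
permutation of reduced-model residuals, and entry stops when a
candidate's p exceeds α *or* the selected model's adjusted R² reaches
the global model's. The variable that crosses the adjusted-R² threshold
is retained and only further entry stops — with a single dominant
predictor, the alternative (rejecting the crossing variable) would
frequently return an empty model in exactly the cases where the signal
is strongest. Calibration is part of the test suite: a pure-noise
response yields an empty model in ≥90% of replicates at α = 0.05, and a
strong single predictor is recovered in >95%. Selection is applied to
the environmental and spatial sets only; the phylogenetic set always
enters whole, since it has exactly two members by design.

Variance partitioning fits the seven OLS models on E, S, P and their
unions, converts each R² to the Ezekiel adjusted R²
(1 − (1 − R²)(n − 1)/(n − p − 1)), and obtains the eight fractions by
inclusion–exclusion: pure E = adjR²(ESP) − adjR²(SP) and cyclically;
shared fractions follow from the singleton and pairwise models; the
residual is 1 − adjR²(ESP). The fraction-sum identity (seven
non-residual fractions summing to adjR²(ESP)) holds to 1e-10 on every
input, by construction and by test. Shared fractions are differences of
adjusted R², not variance components, and can be legitimately negative;
they are reported as computed — suppressing values below zero is a
*display* option of `autoplot()`, never a change to the numbers. Each
pure fraction's significance is a Freedman–Lane permutation partial
F-test of adding that set to the other two (999 permutations by
default). A univariate response makes redundancy analysis collapse to
OLS, so the fractions agree with `vegan::varpart` to 1e-10, which the
suite checks.

When a model would have n ≤ p + 1 the partition refuses to run rather
than report meaningless adjusted R² values; in the pipeline the spatial
candidate set is pre-truncated to the first n − 5 PCNM axes (the axes
are ordered broad-to-fine, so truncation discards the finest-scale
structure first).

## Ecogeographic rules

Bergmann's rule predicts larger bodies, and Allen's rule relatively
shorter appendages, in cooler (higher) environments. The package tests
both at the community level: per site, the unweighted mean (the data are
binary, so presence-weighting is the only defensible choice) of
log10 body size and of relative appendage length over the present
species, regressed on elevation by OLS with a two-sided F-test. Log base
10 is used for body size; the base changes the slope's units but not R²
or p, and it is recorded in the output. Regressions run at order level
(all species) and per family, excluding families that hold under 20% of
the species pool (configurable) or occupy fewer than three sites —
family-level means over one or two species at a handful of sites are
noise. Sites lacking any member of the subset are dropped from that
regression rather than scored as zero. The verdict column compares the
sign of a significant slope with each rule's expectation.

## The synthetic-data generator

The generator emulates the sampling design of a montane small-mammal
survey: a 45-species pool on a pure-birth (Yule) tree, 15 transects of
5 sites spanning 1000–4000 m, two continuous Brownian traits and one
binary trait at prevalence 0.3, and eight environmental covariates that
are linear in elevation plus 10% noise (temperature- and
productivity-like variables decreasing, seasonality-like increasing).
Default parameters *are* the study conditions for all calibration tests;
they were chosen once, on ecological plausibility, and are not tuned per
test.

Pure-birth rather than birth–death trees: one parameter fewer, and
extinction adds nothing to what the downstream statistics need. The
expected root-to-tip depth of the simulator is Σ_{k=2..n} 1/(k·λ), which
the suite verifies against 500 replicates. Brownian traits propagate
from a root value of 0 (K and all distances are translation-invariant,
so the root value is immaterial) with increment variance σ² × branch
length; closed-form checks cover the 2-tip contrast variance and the
shared-path covariance.

Three assembly modes leave three distinct dispersion signatures:

* **filtering** — each species' elevational optimum is the linear
  rescaling of its (Brownian) filter trait onto the elevation range, and
  it occupies exactly the sites within `filter_strength` (default 750 m)
  of that optimum. Ranges are contiguous by construction, so the
  interpolation assumption holds exactly. Co-occurring species share
  similar traits, driving SES of pairwise trait distance strongly
  negative.
* **limiting similarity** — starts from filtering memberships with, by
  default, an *unrestricted* window (the full elevational span), then
  per site repeatedly removes a random member of the closest trait pair
  until all pairwise distances exceed `spacing` (default: a tenth of the
  pool's trait range). Removing a random member, not a deterministic
  one, matters: deterministic thinning retains the same evenly spaced
  species everywhere, and a fixed-margin null then reproduces that
  composition (the narcissus effect), hiding the very overdispersion the
  mode is meant to express. The window default also matters: each mode
  is meant to isolate one process, and a narrow window would superimpose
  filtering's clustering on competition's evenness.
* **neutral** — every species occupies an independently drawn contiguous
  elevational band per transect, unrelated to traits; SES centres on
  zero.

All generators are pure functions of their seed. One master seed drives
the whole pipeline through a documented Lehmer-style splitter
(`split_seed(seed, counter)`), so stages are reproducible in isolation
and jointly.

What the generator does *not* emulate: detection error and sampling
effort gradients, abundance dynamics, dispersal limitation beyond the
transect structure, trait correlations other than shared phylogeny,
non-linear environmental responses, and the reticulate topography of
real mountain systems. Passing calibration tests on these synthetic
bundles therefore demonstrates that the statistics measure what they
claim under known processes — not that real communities are governed by
those processes.

## Numerical choices and degenerate inputs

* Distance matrices must be symmetric to 1e-12 with an exactly zero
  diagonal; the haversine matrix is symmetrized (mean of m and t(m))
  before the vertical term is added to absorb floating-point asymmetry.
* Zero-variance continuous traits make the standardized distance (and
  K) undefined and are refused with the trait named.
* A community matrix with no checkerboard submatrix (e.g. all ones)
  cannot be randomized; draws equal the input and a warning is issued.
* The PCNM positive-eigenvalue tolerance is max(eigenvalue) × 1e-9;
  orthogonality and centring are asserted on the correlation scale,
  which is invariant to the metre-scale eigenvalue magnitudes.
* Exactly collinear candidates are dropped (with a warning naming them)
  before forward selection via pivoted QR rank detection.
* Permutation p-values everywhere use (1 + count)/(n_perm + 1), so they
  are valid test levels and never exactly zero.
* Test and calibration problem sizes — 64-tip trees, 200 Brownian
  replicates for the K calibration, 100 traits × 1000 null draws for
  each D calibration, 200 sites × 999 swaps for SES self-calibration,
  n = 500 for the orthogonal variance-partitioning construction — were
  chosen so Monte-Carlo error sits well inside each property's asserted
  band.

## Open choices, made explicit

* The single-trait distance metric and the species-pool definition are
  conventions, not consequences of the theory; both are arguments
  (`trait_distance(selection=)`, the swap null's input matrix) rather
  than hidden constants.
* Which of D's two p-values a published table reports is often
  ambiguous; both are always emitted.
* Forward selection could alternatively use exhaustive best-subset
  search; the forward variant with double stopping is implemented
  because it is the field's standard and scales to dozens of PCNM
  candidates.
* Family-level trait regressions drop sites lacking the family rather
  than scoring them missing-as-zero.

## Limitations

Abundance-weighted dispersion metrics, alternative null models
(richness-only, frequency-only), Pagel's λ and other signal statistics,
multivariate-response RDA, and GAM/quadratic elevational models are out
of scope. The independent-swap null conditions on both margins; like
any constrained null it can absorb part of a real assembly signal (see
the limiting-similarity discussion above), so SES magnitudes are
conservative for processes that shape prevalence itself.
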