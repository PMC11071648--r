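---
title: "Methods: simulating and estimating lifespan iFC trajectories"
author: "socotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating lifespan iFC trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socotraj)
```

`socotraj` implements a complete inference chain for age-related
trajectories of intrinsic functional connectivity (iFC) between
social-cognition seed networks and canonical cortical networks, exercised
entirely on synthetic cortical data with planted ground truth. This
vignette documents the models, the generator, the numerical choices, and
the decisions taken where the design was genuinely open.

## The synthetic cortex and cohort

Each hemisphere is an icosphere: a recursively subdivided icosahedron
projected to a sphere (radius 100 mm by default, giving a hemisphere area
near the human cortex), with the right hemisphere the mirror image of the
left. Icospheres are closed orientable meshes, so Euler's relation
`V - E + F = 2` holds per hemisphere and the random-field resel counts
below are exact. At the default two subdivisions each hemisphere has 162
vertices with a mean edge length of about 26 mm — a deliberately coarse
stand-in for a downsampled standard cortical grid, chosen so a full
316-subject pipeline runs in seconds.

The 7-network parcellation is grown by multi-source breadth-first
expansion from random seed vertices and mirrored across hemispheres;
patches are therefore contiguous by construction (a property the tests
verify against an independent graph-components oracle). Seed-network maps
are sums of Gaussian geodesic bumps (default: 6 foci per seed, bump FWHM
28 mm, peak weight 4). Two choices deserve comment:

* **Map amplitude.** Meta-analytic seed maps are statistic-valued, with
  peaks well above 1. Giving the bumps peak weight 4 (against
  unit-variance network courses) also keeps the stage-1 spatial
  cross-talk between seed and network signals small — with unit-peak maps
  the estimated seed course picks up correlations of roughly 0.2 with
  every network course, which propagates an age-dependent bias into
  downstream maps.
* **Overlap.** Map overlap is routed through the *last* seed: the moral
  map borrows a fraction (`overlapFrac`) of its foci from the empathy and
  ToM maps, reflecting moral cognition's position at the interface of the
  other two networks, while the empathy and ToM maps stay spatially
  distinct.

Cohort ages are drawn from a normal distribution truncated to
`[8, 83]` years with scale 19.72 y, whose location is moment-matched by a
root search on the closed-form truncated-normal mean so that the expected
mean age equals 44.38 y; sex is assigned to exactly 112 of 316 subjects
by default. The moment matching is what the calibration test (grand mean
over 200 seeded cohorts within 0.5 y) checks.

## The BOLD generator

For subject $j$, each network $k$ gets a unit-variance AR(1) time course
$c_k(t)$; each seed $i$ gets
$u_i(t) = \sqrt{1 - \sum_k w_{ik}^2}\,\xi_i(t) + \sum_k w_{ik} c_k(t)$,
where the couplings
$w_{ik} = \beta_0 + \beta_{lin}\tilde a_j + \beta_{quad}\tilde a_j^2 +
s_j(\beta_{sex} + \beta_{sex,lin}\tilde a_j + \beta_{sex,quad}\tilde a_j^2)$
depend on centered age $\tilde a_j$ (years from the cohort mean — chosen
so the linear and quadratic terms stay decoupled) and sex
$s_j \in \{\pm 1/2\}$. Rows with $\sum_k w_{ik}^2 > 0.95$ are rescaled
(with a warning) so the latent variance stays valid. The vertex signal is
the mixture $x(t,v) = \sum_k M_k(v)c_k(t) + \sum_i Z_i(v)u_i(t) +
\text{noise}$, plus a constant baseline (default 100, so grand-mean
scaling is meaningful) and two broadcast "tissue" signals that give the
nuisance regression something real to remove. This mixture is the minimal
generative form under which dual regression is a consistent estimator,
which is what makes parameter recovery a meaningful test surface.

Defaults: 200 volumes at TR 0.645 s, AR(1) coefficient 0.3, vertex noise
sd 0.5. The run length is deliberately short (desk scale); its main
consequence is statistical, not computational — see *Effect sizes* below.

**What the generator does not emulate:** hemodynamic response convolution,
physiological noise spectra, motion-correlated artifacts (motion traces
are independent smooth random walks), registration error, or a medial
wall. Passing tests therefore demonstrate correctness and calibration of
the *estimators* under a known generative model, not robustness to every
artifact of real resting-state data.

## The planted scenario

The default effect set plants, for the empathy network: a linearly
increasing coupling with dorsal attention (`beta0 = 0.10`,
`betaLin = 0.007`/y), a linearly decreasing coupling with ventral
attention (0.22, −0.007/y), a convex (U-shaped) quadratic with
somatomotor (`betaQuad = 4e-4`/y²), a sex-by-age linear interaction with
control (men increasing, women decreasing, `betaSexLin = 0.018`), and a
sex-by-age quadratic with visual (men U-shaped, women inverted-U,
`betaSexQuad = 5e-4`); for ToM: a concave (inverted-U) quadratic with
ventral attention (0.30, −4e-4/y²); and no effects anywhere for the moral
network. On the somatomotor pair the quadratic's sign was an open choice
— reports of that trajectory are contradictory even within single studies
— and the default plants the U shape; it is configurable.

**Effect sizes.** The band-pass filter (below) leaves roughly 22
independent samples in a 192-volume run, so any per-subject coupling
estimate carries a sampling error near 0.3–0.5 in coupling units. The
default effect sizes come from a power analysis at exactly these
conditions: they are the smallest round values for which the planted
shape dominates that noise at n = 316 (or n = 112/204 for per-sex
classification), while the total squared coupling stays below the 0.95
clip for every subject — clipping would otherwise bend linear
trajectories into spurious inverted-U shapes at the age extremes. The
sex-by-age quadratic pair is intentionally the marginal one: within the
variance budget its per-sex Wald statistic cannot clear ~2.5, so its
recovery is expected but not guaranteed.

## Preprocessing

The default chain follows the conventional enumeration: discard 8 initial
volumes; grand-mean scale to 10,000; regress out an intercept, the two
tissue signals and the Friston-24 motion expansion (parameters, one-volume
lags, and both squared, lagged blocks zero-padded in their first row —
the expansion's column order is fixed here for reproducibility since the
name alone does not pin it down); band-pass 0.01–0.1 Hz; then remove
linear and quadratic trends. Both the band (the conventional
resting-state range) and the nuisance/band-pass order are configurable
because practice varies; the chain's order is recorded in each run's
provenance. Band-pass filtering is frequency-domain masking — exactly
zero-phase, with the DC bin kept only when the low edge is 0 —
and nuisance regression uses an SVD pseudo-inverse with a
`1e-10` relative singular-value tolerance so rank-deficient designs
degrade gracefully. Subject-level scalar covariates (e.g. intracranial
volume or registration cost) are not temporal regressors; they belong in
the group design, which accepts optional covariate columns.

## Dual regression

Both stages are joint ordinary least squares with an intercept: all seed
maps enter stage 1 together (partialling shared variance; a per-seed
marginal mode would ignore overlap) and all stage-1 courses enter stage 2
together. Stage-1 time courses are scaled to unit variance before stage 2
by default so the spatial betas are in signal units and comparable across
subjects. Rank-deficient seed sets abort with the offending map pair
named. Residual variances of both stages are kept on the fit object.

## Group inference

The vertex GLM is OLS with t contrasts on single design columns — the
reported effects are signed (increasing/decreasing, convex/concave), so
single-degree contrasts match the claims better than omnibus F tests (an
F is easy to add downstream since residuals and designs are exposed).
Residual smoothness is estimated from variance-normalized residuals:
$\mathrm{FWHM} = \bar h\sqrt{4\ln 2/\overline{\Delta^2}}$ with
$\overline{\Delta^2}$ the mean squared along-edge difference; resels are
$(R_0, R_1, R_2) = (\chi, 0, \text{area}/\mathrm{FWHM}^2)$ — $R_1 = 0$
because the search region is a closed surface. Cluster correction
Gaussianizes the t map, forms supra-threshold components at `z = 2.3`
(configurable; the threshold is a convention, not derivable), and applies
the standard 2-D expected-Euler-characteristic cluster-size formula.
Inference is two-sided by default (positive and negative excursions
clustered separately, EC densities doubled) because both directions of
age effects are of interest; correction is within each (seed, contrast)
map, mirroring per-network reporting.

Two honesty notes, both encoded as tests. First, the Freedman–Lane
permutation route (max cluster mass, corrected
$p = (1+\#\{perm \ge obs\})/(1+n_{perm})$) is the empirical oracle: it is
exactly calibrated by construction and the test suite checks that RFT and
permutation agree on planted-effect clusters. Second, analytic RFT
assumes a smooth field; at the default mesh the white-noise smoothness is
only ~1.2 vertex spacings, where the analytic cluster p-values become
conservative (the expected cluster size falls below one vertex). The
calibration study therefore uses smooth Gaussian null fields (kernel
FWHM twice the edge length) as the reference regime, and a separate test
asserts that on unsmoothed noise RFT errs only on the conservative side.

## Trajectory models

The default family is the Gaussian location–scale model: $\mu(age)$ and
$\log\sigma(age)$ each quadratic in centered age, fitted by backfitting —
weighted least squares for $\mu$, Fisher scoring with step-halving for
$\sigma$ — to a relative log-likelihood tolerance of 1e-8 (cap: 200
iterations; scale underflow below 1e-10 aborts). It is the simplest
family with age-varying spread, and the quadratic basis matches the
at-most-quadratic shapes under study; a natural-spline basis (df chosen
on a BIC grid over 4–8) is available for less committed smoothing. The
Box–Cox Cole–Green (LMS) family covers skewed positive measures; its
scale model is placed on the outcome sd (`log tau` linear in the basis,
`sigma = tau/mu`) precisely so that fixing the power at `nu = 1` reduces
it exactly to the Gaussian model — the test suite asserts curve agreement
to 1e-4 — and its likelihood omits the lower-truncation normalizer at
zero, negligible whenever `sigma * nu` is small. BCCG optimization runs a
Nelder–Mead search before a scaled BFGS polish; the polynomial
coefficients differ by orders of magnitude, and an unscaled quasi-Newton
start stalls on that surface. Percentile curves (default
10/25/50/75/90) are quantiles of one fitted distribution per grid age and
therefore strictly ordered.

Shape classification refits the location model at degrees 0/1/2 under
the Gaussian likelihood, picks the degree by BIC, then gates the winning
coefficient with a two-sided Wald test at `alpha = 0.05`; a quadratic
winner failing the gate falls back to the linear decision, and anything
ungated is `flat`. The BIC-plus-Wald rule is this package's own
construction — no explicit rule exists to copy — and its false-positive
behavior is characterized by a test (pure noise labeled flat in at least
90% of replicates). With n = 316 the rule's spurious-shape rate is one
to two percent per pair, which is why shape-recovery tests use replicate
majorities rather than single draws.

## Pipeline, seeds and caching

`runPipeline()` drives generate → preprocess → dual regression → GLM →
trajectories from one validated configuration (unknown keys are errors).
A single global seed fans out to per-stage seeds through a fixed affine
map modulo 2³¹−1, so partial reruns are reproducible stage by stage;
stage outputs are cached on disk keyed by a content hash of the stage
parameters and the upstream key, so any upstream change invalidates
everything downstream. Identical configuration and seed give
byte-identical output files, which a test asserts across fresh output
directories.

## Problem sizes

The test suite runs the full pipeline at n = 316 subjects, 200 volumes,
subdivision-2 meshes (324 vertices); error-rate calibration uses 200 null
datasets at n = 60 with 100 permutations each; trajectory calibration
uses n = 2,000. These sizes keep the complete suite in the minutes range
on one CPU while leaving every statistical check adequately powered.

## Known limitations

Spheres are not cortices: there is no medial wall, no curvature
inhomogeneity, and geodesic distances are exact — real surface pipelines
face mesh irregularity this package does not. The generator's noise is
white in space; spatially correlated physiological noise would lower the
effective resel counts. Analytic RFT at coarse mesh resolution is
conservative (see above) — the permutation route is the safer default
when vertex counts are small. And the trajectory models are
cross-sectional: they describe the age-conditional distribution of iFC,
not within-person change.
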