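---
title: "Spatial band morphometry for melanoma prognosis: models and methods"
author: "melbands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial band morphometry for melanoma prognosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(melbands)
```

## The problem

Breslow thickness and mitotic rate are the workhorse prognostic factors in
melanoma, but tumors of similar thickness can behave very differently.
Nuclear morphology — in particular nucleus size — and the spatial
organisation of proliferating tumor cells carry additional prognostic
signal. `melbands` quantifies that signal from multiplex
immunohistochemistry (mIHC) slides stained for DAPI (nuclei), Ki67
(proliferation) and S100 (melanocytic lineage): it gates each marker per
slide, partitions the tumor into superficial, middle and invasive depth
bands, aggregates per-band cell densities and nucleus sizes, and evaluates
the resulting factors in Cox proportional-hazards models with concordance
statistics.

The package consumes *detection exports*, not images: per-cell tables with
centroid coordinates (µm), nucleus area (µm²) and per-channel,
per-compartment mean intensities, plus GeoJSON annotations of the tumor and
epidermis regions and a clinical table. Nucleus detection itself (e.g.
StarDist in QuPath) is upstream and out of scope; detection settings read
from exports are carried as provenance only.

## Two-phase marker gating

Marker positivity is decided per slide with a two-phase adaptive threshold.

**Phase 1 — Otsu split.** The natural log of the compartment-mean
intensities is histogrammed into 256 bins spanning the 1st–99th percentile
of the values (outliers clamp into the end bins, so a single bright speck
cannot move the split). Every interior bin edge is scanned and the edge
maximising the between-class variance

$$\sigma_B^2(t) = \omega_0(t)\,\omega_1(t)\,\left[\mu_0(t) - \mu_1(t)\right]^2$$

is the split; values at or below it form the background $T_0$ (detector
noise and empty compartments), values above form the foreground $T_1$.
When a run of consecutive edges ties exactly at the maximum — as happens
with an empty gap between two spikes — the midpoint of the first and last
winning edges is reported; the tie cannot occur for continuous data.
Working in log space matters: fluorescence intensities are heavily
right-skewed, and on the linear scale the bright population's internal
spread dominates $\sigma_B^2$, dragging the split inside the positive mode.

**Phase 2 — Bayesian Gaussian mixture on $\log T_1$.** The foreground is
modelled as a two-component Gaussian mixture

$$p(x) = \pi_1\,N(x \mid \mu_1, \sigma_1) + \pi_2\,N(x \mid \mu_2, \sigma_2)$$

fitted by MAP expectation–maximisation with a symmetric Dirichlet(1) prior
on the weights and weak, data-centred normal–inverse-gamma priors on the
component parameters (prior strength $\kappa_0 = a_0 = 10^{-3}$, prior
scale from the data variance). The priors guard against collapsing
components while leaving the fit essentially maximum-likelihood; the
penalised log-likelihood trace is non-decreasing at every iteration, which
the tests assert. Initialisation is a deterministic split of $\log T_1$ at
its median, so repeated fits are identical — there is no random restart to
seed. Convergence is declared when the objective changes by less than
$10^{-6}$; the iteration cap is 3000.

**The threshold.** The final positivity threshold solves

$$\pi_1\,N(x \mid \mu_1, \sigma_1) = \pi_2\,N(x \mid \mu_2, \sigma_2),$$

a quadratic in $x$ after taking logs (linear when $\sigma_1 = \sigma_2$),
restricted to the open interval $(\mu_1, \mu_2)$. A cell is positive iff it
lies in $T_1$ and its log intensity is at or above this root — the side of
the higher-mean component. Three guarded departures:

* *No root in $(\mu_1,\mu_2)$* (extreme weight imbalance): the point where
  the two weighted densities are closest is used and `fallbackUsed` set.
* *Unimodal foreground*: when Ashman's
  $D = \sqrt{2}\,|\mu_2-\mu_1| / \sqrt{\sigma_1^2+\sigma_2^2} < 2$ the two
  fitted components describe one population (EM will happily split a single
  mode in half); refining inside it would discard the lower half of the
  positive population, so the Otsu boundary stands and the whole foreground
  is positive, flagged `foregroundUnimodal`.
* *Coincident means* (difference below $10^{-6}$): the gate fails and every
  cell is called negative, with the reason recorded.

Which compartment's mean is gated is configuration, not biology baked into
code; the defaults are Ki67 on the nucleus mean and S100 on the cytoplasm
mean. Thresholds are reported in linear intensity units (the exponential of
the log-space root), and the whole chain is equivariant under a global
multiplicative rescale of the intensities.

## Band geometry

The tumor annotation's boundary is resampled at uniform arc length and its
principal axes computed; the axis most aligned with the direction from the
epidermis centroid to the tumor centroid, oriented into the tumor, is the
**depth axis**. The **estimated thickness** $T$ is the extent of the
boundary's projection onto that axis — the longest distance from the
epidermis-facing edge to the deepest boundary point — and is exported in mm
as the "estimated thickness" factor. On an axis-aligned rectangular fixture
this is exact; under rigid rotation it is stable to well under 1%.

Depth within the tumor is computed by a Euclidean distance transform: the
tumor polygon is rasterised (default 10 µm/pixel; the 0.5 µm scan pixel
size would be needless precision at band scale), the boundary points within
50 µm of the epidermis polygon seed the transform (fallback: the lowest
depth decile of boundary points when no boundary is that close), and each
in-tumor pixel's depth is its distance to the nearest seed. Bands are the
proportional thirds of the PCA thickness, half-open and lower-inclusive:
depth $[0, T/3)$ superficial, $[T/3, 2T/3)$ middle, $[2T/3, \infty)$
invasive. Pixels deeper than $T$ — possible because raster depth is a free
Euclidean distance while $T$ is an axis projection — stay invasive. Band
areas come from pixel counts; on fixtures they sum to the polygon area
within 0.5% and converge under raster refinement.

The **invasive margin** is the deep-facing part of the tumor boundary: the
resampled boundary points at depth $\ge 2T/3$ whose outward normal has a
component above 0.25 along the depth axis. The facing condition is the
package's reading of "the portion of the melanoma opposite the epidermis":
without it, the deep thirds of a tumor's lateral edges would count as
margin, which no pathologist would draw. On a rectangle the margin is
exactly the deep edge.

Cells are mapped to their raster pixel: outside pixels give band
`outside`; in-tumor cells inherit the pixel depth, the thirds band label,
and the Euclidean distance to the margin polyline. Everything is
equivariant under rigid motions of the slide up to raster tolerance.
Multi-fragment tumors are out of scope for this release; coordinates follow
the image convention (y grows downward, so depth grows with y on a
superficial-at-top slide).

## Per-patient factors

Three cell categories are counted inside the tumor: *total* (all in-tumor
cells), *tumor* (S100+), and *colocalized* (S100+ ∧ Ki67+ — proliferating
tumor cells). Per band (plus an overall row) the package computes cell and
colocalized-cell densities (cells/mm², using the raster band areas; the
overall row uses their sum), colocalized-to-total and colocalized-to-tumor
ratios, and mean nucleus areas per category. "Nucleus size" is nucleus
area in µm² throughout. An empty category in a band yields a *missing*
mean — never a zero that would masquerade as tiny nuclei — and a zero
denominator yields a missing ratio. Clinical Breslow thickness stays in mm
and geometry in µm; the single 1/1000 conversion happens at feature
assembly, nowhere inside geometry code.

## Survival evaluation

Cox proportional-hazards models are fitted by `survival::coxph` with the
Breslow tie approximation (the simplest exactly-documentable choice; Efron
is available behind the `ties` argument). Per covariate the package reports
the hazard ratio with a Wald 95% CI and two-sided Wald p-value. Degenerate
designs — constant or collinear covariates, fewer than two events — are
rejected, and monotone likelihoods are flagged as non-convergence. The test
suite pins the fits to an independent grid-search maximisation of the
Breslow partial likelihood on small fixtures.

Harrell's concordance is implemented as explicit pair counting: a pair is
comparable when the strictly earlier time ends in an event; tied risk
scores count half. (This is slightly stricter than
`survival::concordance`, which also compares event-versus-censored pairs at
tied times; on tie-free data the two agree exactly, which a test checks.)
Confidence intervals are bootstrap percentile intervals (default
$B = 1000$): patients are resampled with replacement, the model refitted
and the concordance recomputed per replicate; replicates with fewer than
two events are skipped, with a warning past 10%.

Leave-one-out cross-validated concordance refits the model $n$ times,
records each held-out patient's uncentred linear predictor, scores the
pooled out-of-fold predictors with Harrell's C, and bootstraps the pooled
(predictor, time, event) triples for its CI — one defensible reading of an
LOOCV C-index, stated as such. The univariable screen fits one model per
factor (complete-case per model, factors missing for more than half the
patients excluded, no multiple-testing correction — deliberately, and noted
in output metadata). The multivariable family is the base model
(mitosis + thickness) plus one three-covariate model per invasive-band
nucleus-size factor. Factor correlations are pairwise complete-case Pearson
(Spearman behind a flag) with p-values from the t transform of r and stars
at 0.05/0.01/0.001.

## What the synthetic generator emulates — and what it does not

No cohort data are distributed with the method, so the package ships a
generator whose outputs have the statistical structure the analysis
assumes, with latent truth retained in a sidecar file the pipeline cannot
accidentally consume.

*Slides.* A rectangular (or smoothed-blob) tumor with an epidermis strip on
its superficial edge; cells scattered uniformly at 200/mm² (Poisson total).
Each marker's gated-compartment intensity is drawn from a three-population
log-normal model: positives from the bright component, negatives from a dim
autofluorescence component or — with probability 0.5 — from a dark detector
noise floor. The defaults put 4 within-component standard deviations
between the negative and positive log-means (log-means 3 and 5, sd 0.5,
noise at 0), a clean but not trivial gating problem: after the Otsu phase
strips the noise floor, the surviving foreground is itself bimodal, which
is exactly the regime the mixture phase exists for. Nucleus areas are
normal (mean 40 µm², sd 8) with an optional per-band mean shift keyed to
the cell's true depth.

*Cohorts.* Per-patient features are independent normals; survival times
follow a Weibull proportional-hazards model (shape 1.2, scale 36 months)
with linear predictor $\sum_j \beta_j x_j$; censoring is independent
exponential with its rate calibrated by root-finding so the expected
censored fraction hits the requested value. The demonstration pipeline
couples a latent per-patient severity score to the slide's mean nucleus
area (4 µm²/sd), to clinical thickness (0.3 mm/sd) and to the log-hazard
(0.8/sd), so invasive-band nucleus size is genuinely prognostic and
correlates with thickness — the correlation structure the method is meant
to expose.

The generator deliberately does **not** emulate: spatial clustering or
depth gradients of marker expression, staining batch effects, segmentation
errors (merged/split nuclei), multi-fragment or strongly concave tumors,
informative censoring, or multiple slides per patient. Passing tests
therefore show that the implementation recovers known structure under the
model's own assumptions — not that the biology of any cohort is
reproduced. Cohort-specific published effect sizes are consequently not
acceptance targets here.

## Numerical choices and problem sizes

Determinism is a design requirement: every stochastic routine takes a seed,
a single RNG drives each simulation call (the caller's RNG state is
restored afterwards), bootstrap seeds in the factor screen derive from the
factor *name* so permuting the factor list permutes nothing else, and
rerunning the pipeline with one seed reproduces its output files byte for
byte. Variance floors ($10^{-10}\times$ data variance) keep EM finite on
adversarial input; polygon self-intersection and schema violations are
rejected at the I/O boundary rather than coerced.

The shipped test and demo sizes are chosen for desk-scale runs: slides of
2–3 mm × 4–6 mm at 150–200 cells/mm², 10 µm rasters, cohorts of 40
(pipeline demo) to 400 (estimator calibration) patients, 100-replicate
coverage studies, and bootstrap $B$ of 100–500 in tests versus the default
1000 in analysis use. The full demonstration pipeline — simulation, gating,
banding, features, screen, multivariable models with LOOCV, correlations —
runs in about a minute on one core.

## Known limitations

The thirds partition inherits the ambiguity of the source method: depth is
measured by distance transform from the superficial boundary while the
cutoffs are thirds of a PCA projection; these coincide on convex tumors but
can diverge on strongly concave ones. The margin's deep-facing rule uses a
fixed 0.25 normal-alignment cutoff. LOOCV concordance on pooled uncentred
predictors is one of several possible definitions. The gating defaults
assume intensities on a common per-slide scale; between-slide normalisation
is upstream of this package.
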