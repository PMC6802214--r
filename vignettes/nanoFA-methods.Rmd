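---
title: "nanoFA: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanoFA: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoFA)
```

`nanoFA` quantifies the three-dimensional architecture of focal adhesions
(FA) from single-molecule localization microscopy data — specifically the
iPALM setting, where each detected fluorophore carries an isotropic 3D
position with z measured as distance from the coverslip — together with the
adhesion-scale morphology and dynamics read-outs used for colony-level
statistics. This vignette explains the models, the estimator choices, what
the synthetic generators do and do not emulate, and where the design was
genuinely open.

## Vertical layer model

Within an adhesion region, a protein's vertical positions are modelled as a
Gaussian layer. The analysis is deliberately histogram-based: z values are
binned at 1 nm (half-open bins `[e, e + 1)`) and the bin counts are fitted
by unweighted least squares with

$$ c(z) = A \exp\!\left(-\frac{(z - Z_\mathrm{centre})^2}{2\,s_\mathrm{vert}^2}\right), $$

or, for proteins with two coexisting layers (actin, alpha-actinin-1), by a
sum of two such terms with independent centres and widths. Fitting the
binned counts rather than maximizing the raw-z likelihood is a fidelity
choice: the histogram fit is the field's canonical procedure for these data,
and on clean Gaussian layers the two estimators agree to well within the
reported tolerances (the tests check the histogram fit against sample
moments across seeds). A precision-weighted or maximum-likelihood mode would
be a natural extension but is intentionally out of scope.

Assumptions worth stating: localizations within an ROI are treated as
exchangeable draws from the layer distribution (no drift or tilt of the z
axis), the background under the peak is negligible or has been cropped away
by the ROI, and 1-nm bins are fine relative to every reported layer width
(`s_vert` of 8-20 nm).

### Initialization, restarts and degeneracy

The single-Gaussian fit starts from the histogram's weighted moments and
uses Levenberg-Marquardt (`minpack.lm::nlsLM`) with bounded parameters
(`A >= 0`, centre within the histogram range, `sigma >= 0.1` bin widths),
up to 500 iterations, and a handful of deterministic perturbation restarts.

The two-Gaussian fit initializes centres from the two most prominent
separated local maxima of the 3-bin-moving-average-smoothed counts, with
quartile-based restarts; per-component widths are initialized from the local
half-width at half-maximum around each guessed centre, which keeps the
optimizer honest when the peaks are much narrower than the overall spread.
Components are always reported in ascending `Z_centre` ("low" then "high"),
so relabeling the input cannot change the result. Two safeguards deal with
near-degenerate data:

- among converged runs whose RSS ties the best within 0.5%, the solution
  with the smaller centre separation wins — a split of one true layer into
  two never beats the collapsed solution by more than noise;
- when the best two-component fit does not beat the single-Gaussian fit by
  the model-selection margin (below), the collapsed solution (both
  components at the single-Gaussian centre) is returned and flagged
  degenerate. The degeneracy criterion itself is declared, not inferred:
  `|mu_1 - mu_2| < max(sigma_1, sigma_2) / 2`.

### Model selection

Whether a profile has one or two layers is decided by a least-squares BIC,
`n_b log(RSS / n_b) + p log(n_b)` over the `n_b` bins with `p` = 3 or 6
parameters: two components are claimed only when their BIC is lower by at
least 10 *and* the fit is non-degenerate. The threshold is a deliberate,
conservative convention — the data this models report dual peaks only
"where observed", with no stated rule, so the package fixes one that is
deterministic and testable. Histograms with fewer than 200 localizations
additionally carry a low-confidence note.

### Combining ROIs

`summarizeLayers()` combines per-ROI fits by arithmetic averaging of
`Z_centre` and `s_vert` (the default, matching the convention of averaging
per-region fits), and reports box statistics: median, 1st/3rd quartiles,
and whiskers at median ± 1.5 × IQR. The alternative — pooling localizations
across ROIs and fitting once — is available by construction: concatenate
the z values and fit the pooled histogram. Averaging is the default because
per-ROI fits weight each adhesion equally rather than by localization
count; the two modes agree when layers are homogeneous across ROIs and
differ when they are not, which is itself diagnostic.

Note that for bimodal proteins the peak-to-peak separation of the fitted
centres and the width of the inter-layer trough are different quantities;
the package reports fitted centres (and their difference) and makes no claim
that the trough width equals the separation.

## Tag geometry

For a molecule tagged at both ends, `tagSeparation()` reports
`delta_z = Z_centre(C) - Z_centre(N)` from two single-component summaries.
Verdicts: "C-above-N" (`delta_z > 0`), "N-above-C" (`delta_z < 0`), or
"level" when `|delta_z|` is at or below a 5-nm resolution floor — a
configurable convention motivated by the sub-20 nm instrument class. The
inclination angle is `theta = asin(|delta_z| / L)` for an assumed full
molecular length `L`. `L` is a required user input: the package refuses to
assume a literature constant, because the angle is only as meaningful as the
length it is computed from, and output metadata records that the angle used
summary-level (not per-ROI) separations.

## Lateral architecture

Three descriptive metrics quantify the within-adhesion organisation:

- `lineProfile()` averages image intensity perpendicular to a segment over a
  stated width (nm), samples at pixel pitch and normalizes to a maximum of
  1; an all-zero strip is an error because normalization is undefined.
- `edgeEnrichment()` operationalizes "ring-ness" as the ratio of
  localization density in the rim (points within `rim_width`, default
  200 nm, of the polygon boundary) to the density in the remaining
  interior. Region areas are computed by counting fine-grid cell centres
  (400 x 400 over the bounding box), which is deterministic and keeps the
  metric invariant under rigid motions up to grid resolution (the tests
  bound the violation at 2%). An empty interior yields an infinite-ratio
  sentinel with a warning rather than an error. The scalar definition is
  this package's own; the source imagery shows profiles only.
- `fitParaboloid()` fits `z = c0 + c1 x + c2 y + c3 x^2 + c4 xy + c5 y^2`
  by OLS (coordinates centred internally for conditioning; quadratic
  coefficients are translation-invariant) and reports the eigenvalues of
  the Hessian `[[2 c3, c4], [c4, 2 c5]]` as principal curvatures, positive
  = cup opening upward. Both |curvatures| below `1e-5 /nm` (configurable)
  is a "flat" verdict. The quadratic degree is an assumption — the shape
  being tested for is a paraboloid — and exact polynomial surfaces are
  recovered to machine precision.

## Adhesion areas: the hyper-exponential model

Adhesion areas are heavy-tailed and are modelled as a weighted sum of two
exponential densities with means (characteristic areas) `a1 < a2`:
small, transient adhesions populate the `a1` component and the large
cornerstone-type adhesions the `a2` component. The canonical estimator here
is maximum likelihood via EM on the *raw* areas — statistically cleaner than
fitting a binned histogram, free of bin-width choices — with 5 deterministic
quantile-based starts, best-likelihood selection, and the `a1 < a2` ordering
restored after convergence (so label-swapped starts converge to the same
reported fit). The per-iteration log-likelihood trace is retained and
checked non-decreasing. Standard errors come from the numerically
differentiated observed information. Effectively single-exponential data
(relative component gap under 1%, or a boundary weight) is flagged
degenerate rather than rejected; in that case the dominant component's mean
equals the sample mean, which is the exponential MLE — the tests use this
identity as an independent check.

Segmentation ahead of the area fit uses a global Otsu threshold by default
(the upstream tooling's threshold being unstated, a fixed threshold can be
supplied), 8-connected components, and a 0.05 um² minimum area. The colony
edge/centre partition takes the colony pixels within a fixed-thickness strip
of the boundary (distance transform, image border counting as boundary),
with the two standard presets: 40 px for fixed-cell analysis and 5 um for
live imaging.

## Dynamics

`trackAdhesions()` links regions frame to frame by maximal pixel overlap —
deliberately simple and fully deterministic: ties break by larger overlap
then smaller label, splits keep the identity on the largest fragment, and
there is no gap closing (a one-frame disappearance ends a track). Lifetimes
are frames-present × frame interval, capped at 105 minutes by default (the
shortest-replicate convention), binned at 15 min; maximal sizes bin at
0.5 um². Coverage is exact pixel accounting per frame and class. Bin widths
are package choices, configurable, not claims about any source figure.

## What the synthetic generators emulate — and what they do not

The generators exist so every stage can be tested against known ground
truth, at the study conditions the reference table records:

- `simulateLocalizations()` draws z from the component Gaussians of a
  `LayerSpec` (weights as stated; defaults equal) and lateral positions from
  one of: uniform disc (radius 1000 nm by default — the micrometre scale of
  cornerstone FA), edge ring / uniform annulus `[R - rim, R]` (rim 200 nm),
  cup (disc with `k r^2` added to z, emulating the vinculin cup; no
  quantitative curvature is reported anywhere, so the default
  `k = 1e-4 /nm` is a free parameter of this package), or wall (rim annulus
  with a vertical offset, the kank geometry). Optional background is
  uniform in z over 0-300 nm and uniform laterally, standing in for the
  cytoplasmic fraction around adhesions.
- `simulateAreas()` draws from the two-exponential mixture. The reported
  characteristic areas are `a2` = 4.2 um² (uniform surfaces) and 1.8 um²
  (constrained surfaces); `a1` and `w` are not reported anywhere, so the
  package adopts `a1 = 0.8` um², `w = 0.6` for the uniform condition and
  `a1 = 0.5` um² (necessarily below 1.8) for the constrained condition —
  chosen once as plausible small-adhesion statistics, stated here, and not
  revisited.
- `simulateColonyMovie()` renders disjoint elliptical adhesions in a
  polygonal colony: edge adhesions born at frame 1, growing log-linearly to
  their maximal size over 5 frames and persisting (stable cornerstone
  behaviour); centre adhesions born over time (Poisson, 0.3/frame) and
  dying after exponential lifetimes (mean 25 min) — the qualitative
  edge-stable/centre-dynamic contrast. Defaults: 256 x 256 px at
  0.2 um/px, a 105-frame, 1 min/frame movie.

Deliberately not modelled: photophysics (blinking, photon budgets,
localization-precision heterogeneity), camera noise, drift, z-calibration
artefacts, adhesion merging/sliding, and any spatial correlation between
neighbouring adhesions. Passing recovery tests on these generators
demonstrates that the estimators are unbiased and stable at realistic sample
sizes and geometries; it does not certify performance on real data whose
failure modes live exactly in the unmodelled terms (drift, background
structure, touching adhesions).

Every generator consumes an explicit integer seed, uses one locally scoped
RNG stream, restores the caller's RNG state, and is bit-reproducible.

## Problem sizes and tolerances

The recovery suites run at 20,000 localizations per protein cloud (about
the scale of a well-sampled adhesion ROI), 50,000 areas per mixture fit, and
10 seeds per condition; at these sizes single-layer centres are recovered
within ±2 nm, two-layer centres within ±3 nm, and the characteristic area
`a2` within 5% (median). Optimizer settings are fixed in code: 500
iterations, `ftol = 1e-10` for the layer fits; EM stops at a relative
log-likelihood change of 1e-10 or 500 iterations.

## Known limitations

- The layer fits assume an isolated peak per component; strongly overlapping
  background (cytoplasmic) structure under a peak will bias `s_vert` upward.
- `edgeEnrichment()`'s grid-based areas limit accuracy for very thin rims
  (rim width below a few grid cells of the polygon's bounding box).
- Tracking has no gap closing and no merge handling: blinking segmentation
  (a mask flickering off for one frame) splits tracks, which biases
  lifetimes downward on noisy real movies.
- ROIs are explicit inputs; the package does not attempt to reproduce
  manual adhesion outlining, and no trainable segmentation is included.
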