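# nanoFA

Nanoscale vertical and lateral architecture of focal adhesions from 3D
single-molecule localization data.

Human pluripotent stem cell (hPSC) colonies are encircled by unusually large,
stable "cornerstone" focal adhesions (FA). Interferometric PALM (iPALM)
resolves the proteins inside such adhesions with sub-20 nm, isotropic 3D
precision, and the resulting localization tables reveal a vertical lamination
of the adhesion: a membrane-proximal integrin-signalling layer (paxillin), a
force-transduction layer (talin, vinculin), and actin-regulatory layers that
in cornerstone FA split into two discrete strata. `nanoFA` implements the
quantitative analyses this kind of data calls for, as a reusable, tested R
package:

- **Vertical layer decomposition** — 1-nm z histograms and least-squares fits
  of `A exp(-(z - Z_centre)^2 / (2 s_vert^2))`, or a sum of two such
  Gaussians with independent centres and widths for bimodal profiles
  (actin, alpha-actinin-1), with conservative BIC model selection
  (`zHistogram()`, `fitGaussianLayer()`, `fitTwoGaussianLayers()`,
  `selectLayerModel()`, `summarizeLayers()`).
- **Tag-pair geometry** — signed vertical separation `delta_z = z_C - z_N` of
  N-/C-terminally tagged molecules, orientation verdicts (talin: C above N;
  hPSC vinculin: head above tail, i.e. N above C), and the inclination angle
  `theta = asin(|delta_z| / L)` of an extended molecule of length `L`
  (`tagSeparation()`, `inclinationAngle()`, `layerOffset()`).
- **Lateral architecture** — normalized line intensity profiles, the
  rim/interior density ratio that quantifies edge-ring enrichment (integrin
  beta-5, talin), and quadratic surface fits with principal curvatures that
  separate flat layers (paxillin) from the cup-shaped vinculin distribution
  (`lineProfile()`, `edgeEnrichment()`, `fitParaboloid()`).
- **Adhesion morphology** — Otsu segmentation with 8-connected labeling,
  edge-strip/centre colony partition, and a hyper-exponential model of
  adhesion areas, `w Exp(a1) + (1 - w) Exp(a2)` with characteristic areas
  `a1 < a2`, fitted by EM on raw areas (`segmentAdhesions()`,
  `partitionEdgeCentre()`, `fitAreaMixture()`).
- **Adhesion dynamics** — overlap-based tracking of labeled movies, lifetime
  (capped at 105 min) and maximal-size frequency distributions, and per-class
  colony coverage (`trackAdhesions()`, `lifetimeDistribution()`,
  `maxSizeDistribution()`, `coverageFraction()`).
- **Synthetic data with ground truth** — generators for layered localization
  clouds (`simulateLocalizations()`), hyper-exponential area samples
  (`simulateAreas()`) and colony movies with stable edge / dynamic centre
  adhesions (`simulateColonyMovie()`), all bit-reproducible by explicit seed.
  `cornerstoneLayers()` ships the reference `(Z_centre, s_vert)` layer table
  the generators and recovery tests run at.

## Worked example

```r
library(nanoFA)

## simulate a paxillin cloud at the reference layer values and fit it
tab <- simulateLocalizations(referenceLayerSpec("paxillin"), seed = 1)
fitGaussianLayer(zHistogram(tab))
#> LayerFit (1 component, n = 20000)
#>   Z_centre = 55.8 nm, s_vert = 8.5 nm, weight = 1.00

## the bimodal actin profile is detected and decomposed
actin <- simulateLocalizations(referenceLayerSpec("actin"), seed = 1)
sel <- selectLayerModel(zHistogram(actin))
sel$modelOrder
#> [1] 2
sel$fit2
#> LayerFit (2 components, n = 20000)
#>   Z_centre = 99.7 nm, s_vert = 14.5 nm, weight = 0.50
#>   Z_centre = 155.7 nm, s_vert = 14.2 nm, weight = 0.50

## vinculin tag geometry: the N-terminal (head) layer sits above the tail
vn <- summarizeLayers(list(fitGaussianLayer(zHistogram(
  simulateLocalizations(referenceLayerSpec("vinculin_N"), seed = 2)))))
vc <- summarizeLayers(list(fitGaussianLayer(zHistogram(
  simulateLocalizations(referenceLayerSpec("vinculin_C"), seed = 3)))))
tagSeparation(vn, vc, protein = "vinculin")
#> TagGeometry 'vinculin': z_N = 100.4 nm, z_C = 76.5 nm, delta_z = -23.9 nm (N-above-C)

## characteristic adhesion areas by EM on a hyper-exponential sample
fitAreaMixture(simulateAreas(0.8, 4.2, w = 0.6, n = 50000, seed = 4))
#> AreaMixtureFit (n = 50000): a1 = 0.813 um^2, a2 = 4.28 um^2, w = 0.61
```

The fitted `Z_centre` values recover the generating layer centres (paxillin
55.7 nm; actin 99.6 and 155.4 nm) to well under a nanometre-scale error, the
vinculin verdict is head-above-tail with a ~24 nm separation, and the
recovered characteristic area `a2` matches the generating 4.2 um².

A thin command-line wrapper over the same functions is installed at
`inst/scripts/strata.R` (stages `simulate`, `zprofile`, `areas`; each run
writes a `manifest.json` with the full effective configuration, seeds and
input hashes).

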