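---
title: "Methods: hyperspectral plant-health monitoring with hyperleaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral plant-health monitoring with hyperleaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperleaf)
```

## The measurement problem

Line-scan (pushbroom) hyperspectral cameras build an image one scan line at
a time while a stage translates the sensor over stationary plants. Each
acquisition yields a *hypercube*: a 3-D array indexed by scan line (Y),
cross-track sample (X) and spectral band (lambda). A single overhead pass
collects a broadband-illuminated reflectance cube; the return pass under
UV-A excitation collects a chlorophyll-fluorescence cube of the same scene.
`hyperleaf` implements the downstream software chain for such a system:
calibration arithmetic, BIL cube I/O, reflectance conversion, plant
segmentation, reflectance/fluorescence registration, spectral feature
extraction, and drought-stress classification — plus a synthetic phantom
generator that stands in for the instrument so that every stage is testable
end to end.

## Calibration and scan planning

The camera's spectral axis is calibrated by regressing known pencil-lamp
emission-line wavelengths on detector pixel indices
(`fit_spectral_calibration()`, ordinary least squares). The shipped preset
maps detector pixels 401–700 to 408–1001 nm — 300 collected spectral pixels
at a 1.98 nm interval. Only the endpoint correspondence is encoded in the
preset; the API accepts any table of (pixel, wavelength) pairs, so a user
with their own lamp lines refits rather than trusting ours.

Along-track geometry follows from kinematics: the stage speed is tied to the
exposure time by the reciprocal law V = 1/T, so `plan_scan(0.05, 800, 800)`
gives 20 mm/s, a 40 s pass, and 1 mm/pixel. The law is treated as exact
with an optional speed override, because the underlying frame-rate
constraint is hardware-specific. Cross-track resolution is the IFOV length
divided by the sample count (484 mm / 1936 = 0.25 mm/pixel).

## Cube handling

Cubes are stored on disk as band-interleaved-by-line (BIL) binary payloads
with plain-text ENVI-style headers; 12-bit detector counts live in 16-bit
unsigned containers. In memory the axis order is (line, sample, band),
which keeps per-pixel spectra contiguous for analysis; the reader performs
the transpose. Byte order defaults to little-endian with a header override.
One deliberate deviation from a language-neutral design sketch: all spatial
coordinates and ranges in the R interface are 1-based and inclusive — the
native R convention — rather than 0-based half-open. A mixed convention
inside an R package invites off-by-one errors at every call site.

## Reflectance conversion

Raw cubes are first smoothed by non-overlapping block means: groups of 3
along the spectral axis and groups of 4 along the cross-track axis
(`bin_cube()`), turning a 1200x350x300 acquisition into a 300x350x100 cube
with a 5.94 nm interval. Trailing pixels that do not fill a block are
dropped; the instrument's full-scale geometries divide exactly. No
averaging is applied
along the scan direction.

Flat-field correction divides each pixel spectrum by the mean spectrum of a
reflectance-standard panel mounted at the scan origin and multiplies by the
panel's nominal reflectance (100%): `reflectance = I / I_panel x 100`. No
dark-frame subtraction is performed by default — the conversion is a pure
panel ratio — but an optional dark spectrum is accepted for cameras that
need it. Values above 100% (specular glints) are kept and counted rather
than clipped. The panel region is configuration, not auto-detection, since
the panel is physically bolted to one end of the chamber.

## Segmentation by two-band ratio

Plant/background separation uses a screening search over all ordered band
pairs: for every pair (l1, l2) the Pearson correlation between the
per-pixel ratio R(l1)/(R(l2)+epsilon) and integer class labels (lettuce 1,
soil 2) is computed, and the pair with the largest |r| is selected
(`band_ratio_search()`). Pearson correlation is used because the labels are
a two-level numeric code; the class coding affects only the sign of r.
Epsilon defaults to 1e-6 times the 99th-percentile reflectance — large
enough to guard masked or dark denominators, small enough to leave real
ratios untouched. Zero-variance ratio vectors get r = 0 rather than NaN,
and exact ties break toward the lexicographically smallest wavelength pair.
Spectra enter per pixel rather than ROI-averaged (an averaging switch
exists): per-pixel spectra carry the within-class variance that makes the
correlation ranking meaningful.

The winning ratio image is binarized with Otsu's method on a 256-bin
histogram spanning [min, max], with pixel values represented by bin centers
(`otsu_threshold()`); the mask polarity follows the sign of the selected
correlation. The same machinery applied to control-vs-drought leaf spectra
selects the stress ratio in the red-edge region. Because inverting a ratio
is a near-neutral transform for |r|, the stress search can return the
planted pair in either orientation; downstream reporting canonicalizes to
the orientation with the stressed class elevated (positive r under
control=1/drought=2 coding).

## Registration

The reflectance and fluorescence passes traverse the same track in opposite
directions, so their misalignment is, to a good approximation, a pure
horizontal integer shift. `estimate_shift()` maximizes normalized
cross-correlation over integer offsets (horizontal-only by default, full
2-D behind a flag) using a printed dot-grid target; sub-pixel and rotational
registration are out of scope. `apply_shift()` translates every band
identically and zero-fills vacated pixels so they drop out of masks. A
score below 1 reports residual mismatch; on noiseless targets recovery is
exact, which the tests verify against an independent FFT cross-correlation
oracle.

## Feature extraction and the average-window filter

Masked spectra are summarized per band (mean, SD, n). Leaf area is the
plant-pixel count of each mask; daily control-vs-drought comparisons use a
Welch two-sample t-test (safer than pooled variance when drought shrinks
both the mean and the spread; a pooled option exists) with the percent
deficit (mean_c − mean_d)/mean_c x 100.

The average-window filter reduces masked pixels to 3x3 window-mean spectra
while discarding high-variation areas such as leaf margins. The masked
bounding box is tiled from its top-left corner; windows containing any
unmasked pixel are set aside (they are exactly the mixed margin windows the
rule targets) and counted separately, as are pixels left over by the
tiling, so the accounting `9 x kept + removed + partial + leftover = masked`
is exact. One interpretive decision deserves emphasis: computing the mean M
and SD of each 3x3 window *from its own nine pixels* makes the removal rule
vacuous — among nine values none can sit more than 8/3 sample SDs from their
own mean, so an M ± 3SD fence could never fire. M and SD are therefore
computed **globally** over all masked pixels of the driver band image (the
high-reflectance 815 nm band by default) and applied per window: a window is
removed when more than 10% of its nine pixels (i.e. one or more) fall
outside the global fence. This is the only reading under which the
procedure does anything, and it is flagged here as a documented
interpretation.

Pseudo-RGB renderings take three configurable bands (defaults 640/550/460
nm — unspecified upstream, chosen as generic R/G/B centers) with a
percentile contrast stretch per channel, which makes the rendering invariant
to global intensity scaling.

## Classification protocol

Window-mean spectra labeled by tray treatment feed seven classifier
families: Naive Bayes, decision tree, ensemble (random forest), k-nearest
neighbors, RBF-kernel SVM, a single-hidden-layer neural network, and
regularized discriminant analysis. The evaluation protocol is stratified
5-fold cross-validation re-randomized over 10 repeats; the overall accuracy
is the mean of the ten per-repeat accuracies, the confusion matrix and ROC
pool the out-of-fold predictions, and all randomization derives from one
seed. `compare_families()` shares the same fold assignments across
families so comparisons are paired. Stratification is the natural default
for a balanced two-class design. Windows from the same tray may share
folds, matching a per-spectrum protocol; this is optimistic whenever
windows from one plant resemble each other, which is why the phantom
experiments below put plant-level random effects into the generator rather
than pretending windows are independent.

Hyperparameters are chosen per training fold by an inner 5-fold search
minimizing classification error with equal misclassification costs, over
small budgeted grids: tree cp in {0.001, 0.01, 0.05}; random-forest mtry in
{sqrt(p), p/3} at 200 trees; k in {1, 3, 5, 9, 15, 25}; SVM cost in
{0.1, 1, 10} x gamma in {0.1, 1, 10}/p; network size in {3, 8} with decay
in {0.01, 0.1}. Gaussian Naive Bayes has no tuned hyperparameter. The
"optimizable discriminant" is implemented in-package as shrinkage
discriminant analysis: Sigma(gamma) = (1−gamma) Sigma_hat + gamma
mean(diag(Sigma_hat)) I, searched over gamma in {0, 0.1, ..., 1} crossed
with {linear, quadratic}; shrinkage is what makes a discriminant fit
well-posed when the band count (100) approaches the per-class sample count,
and settings whose covariance is singular are simply skipped by the inner
search.

## The phantom generator

`render_scene()` fabricates paired reflectance/fluorescence cubes of a
lettuce-on-soil scene with a reference-panel strip, pots in a 2x3 tray (six
plants per treatment, as in the pilot drought study), per-pixel class
ground truth, and a known fluorescence shift (default 10 px left). Leaf
endmembers are parametric: a flat pigment-free background, logistic red-edge
switch near 720 nm, Gaussian chlorophyll-a absorption at 672 nm, blue
absorption, and a green relief peak at 559 nm, all scaled by a chlorophyll
level so the spectrum flattens as chlorophyll vanishes. Fluorescence is a
four-Gaussian emission (450, 530, 690, 732 nm) with the red peaks dominant.
Drought is modeled as a x1.15 reflectance plateau over 685–700 nm — the
red-edge shoulder elevation that distinguishes stressed plants — plus an
optional leaf-area deficit fraction for late-stage stress; raw 12-bit
variants under a synthetic LED illumination spectrum exercise binning and
flat-field correction.

The within-class covariance structure of the phantom is not decoration: it
decides which band pair the correlation search selects, so it was designed,
once, before any acceptance checks were frozen. Under naive iid pixel
noise, a ratio of a deep-absorption band to a NIR band separates leaf from
soil almost noiselessly and the search selects it — not the green/red pair
that close-range measurements actually select. The generator therefore
encodes the variability a real canopy has: a per-pixel multiplicative
brightness factor (3%, cancels in ratios), additive detector noise (0.4
percent-reflectance), small chlorophyll-level jitter, pigment
band-*position* jitter (SD 1 nm at 672 nm; SD 2 nm for the green peak),
leaf structural NIR variability (15% SD beyond the red edge, from leaf
stacking and angle), soil color-slope jitter plus variable soil blue
absorption, and partial-volume leaf contamination of soil pixels within 4 px
of the rosette margin. Pot-level random effects (chlorophyll, deep-NIR
canopy density, brightness gain, band position, and a lognormal drought
response with SD 0.35 on the log effect) make plants differ the way the
pilot study's non-uniform watering made them differ; they are what keeps
Naive Bayes honest while the covariance-aware discriminant stays above 90%.

What the phantom does *not* model: radiative-transfer leaf optics, 3-D
canopy geometry and its illumination effects, specular glints, water-band
NIR signatures of drought, or instrument artifacts beyond additive noise
(second-order spectral contamination is removed optically in the real
system). Passing tests on the phantom therefore demonstrate that the
*pipeline* recovers effects of the modeled kind at realistic
signal-to-noise — not that the classifier accuracies would transfer to any
particular real dataset.

## Numerical choices and degenerate inputs

* Binning uses floor division; factors exceeding a dimension are errors.
* Flat-field requires strictly positive panel means in every band.
* The Otsu histogram always spans [min, max] with 256 bins; constant images
  are a degenerate-histogram error. The threshold is affine-equivariant.
* The ratio-search surface excludes the diagonal; |r| ties break to the
  smallest wavelength pair.
* Shift search ties break toward the smallest shift magnitude.
* The discriminant's gamma = 0 settings can be singular for p > n; the
  inner search skips them rather than failing the fit.
* All stochastic steps (scene rendering, fold assignment, stochastic
  fitters) are driven by explicit integer seeds; rendering a scene sets the
  R session seed.

## Problem sizes used in the tests

The shipped test and acceptance workloads run on scaled-down scenes chosen
as the package's own defaults: single-pot scenes of 96 x 96 reduced pixels
and 2x3 tray scenes of 80 x 102 reduced pixels (raw variants 4x wider and
300 bands), six pots per treatment, 100 spectral bands. The stress
band-ratio analysis pools five simulated scan days per treatment, mirroring
the weekly pooling of the original protocol; classification datasets hold
roughly 350 window-mean spectra. These sizes preserve the structure of the
full-scale acquisitions (panel strip, tray layout, band grid) at a fraction
of the memory.

## Known limitations

* Only BIL interleave is supported; BIP/BSQ readers are out of scope.
* Registration is integer translation; scenes needing rotation or scaling
  (e.g. different exposure times between passes) need external tools, and
  `register_pair()` is honest about this by reporting its correlation
  score.
* The correlation search is two-class; multi-class label screening is not
  implemented.
* Per-spectrum cross-validation on windows from the same plant remains
  optimistic; a group-aware split is a straightforward extension but is not
  the protocol being reproduced here.
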