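---
title: "Quantifying active-zone protein puncta in dual-color STED images"
author: "stedpuncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying active-zone protein puncta in dual-color STED images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedpuncta)
```

## The measurement problem

Presynaptic active zones of the neuromuscular junction (NMJ) contain
scaffold proteins (Bassoon, Piccolo) and P/Q-type voltage-gated calcium
channels (VGCCs) that appear, under stimulated emission depletion (STED)
microscopy, as compact fluorescent puncta of roughly 100--125 nm full width
at half maximum (FWHM) at a 20 nm pixel pitch.  The quantities of interest
are:

* per-punctum size (FWHM of a line profile through the punctum),
* per-synapse signal intensity per area and mean intensity per punctum,
* puncta density over the synapse (the acetylcholine-receptor cluster mask),
* cross-channel arrangement: how many puncta of one protein associate with
  each Bassoon punctum, including the distinctive Piccolo--Bassoon--Piccolo
  "sandwich" in which two Piccolo puncta about 100 nm apart flank one
  Bassoon punctum,
* group comparisons (e.g. adult versus aged animals) by two-tailed unpaired
  t-tests.

Because raw microscope data for this kind of study are typically not
deposited, the package is built around a synthetic scene generator with
exact ground truth.  Every stage of the pipeline is validated against
scenes whose punctum positions, widths, amplitudes and motif memberships
are known, and the same generator doubles as a power/calibration tool.

## The image model

A scene (`buildScene()`) places motifs inside a parametric synapse mask:

* `sandwich`: two flank puncta in one channel separated by
  `flank_separation_nm` (default 100 nm) with a center punctum of the other
  channel at their midpoint;
* `tandem_sandwich`: the sandwich repeated in tandem, sharing the middle
  flank punctum;
* `coloc_pair`: one punctum per channel at a common position;
* `solitary`: a single punctum in one channel.

Each punctum is rendered (`renderChannel()`) as an isotropic 2D Gaussian
with $\sigma = \mathrm{FWHM}/2.3548$, evaluated at pixel centers, on a
uniform background -- the conventional approximation of an effective STED
point-spread function.  Noise (`applyNoise()`) follows the standard
photon-counting model: Poisson shot noise plus Gaussian read noise
(default SD 1 count), clipped at zero.  Coordinates are continuous
nanometers with the origin at the top-left corner; the center of pixel
$(r, c)$ (1-based rows/columns) is at $((c-0.5)\,p, (r-0.5)\,p)$ for pixel
pitch $p$.

Default study conditions mirror the acquisition geometry the pipeline
targets: 20 nm pixels (a full field is 970 x 970 px, i.e. 19.4 um on a
side; examples and tests use 128--256 px crops for desk-scale runtimes),
punctum FWHM drawn from 100--125 nm, amplitudes 110--200 counts over a
background of 10 (peak SNR of at least ~10), motifs at least 400 nm apart.
Synapse-to-synapse variability can be emulated through `n_range` (puncta
counts drawn per scene) and `amplitude_scale_range` (a scene-wide
brightness factor); real NMJs vary several-fold in both respects.  Two
placement margins keep the ground truth unambiguous: motif centers stay
400 nm from the image edge (border effects) and 100 nm inside the mask
boundary, so "inside the mask" is never decided by sub-pixel centroid
noise.

What the generator does **not** emulate: anisotropic or non-Gaussian PSFs,
depletion-beam artifacts, antibody-size displacement, out-of-focus light,
spectral bleed-through, tissue autofluorescence, or 3D structure.  Passing
tests therefore demonstrate correctness of the measurement algorithms under
a faithful geometric and photometric model, not robustness to every
property of real micrographs.

## Thresholding

`autoThresholdLight()` implements histogram-trough thresholding for bright
objects: the modal gray-value bin of the masked pixels is the background
peak; the brightest-side object peak is the highest-count strict local
maximum; the threshold is the upper gray edge of the minimal-count bin
strictly between the two (ties resolve toward the dimmest bin).  Integer
images whose range spans at most 256 gray levels are binned one bin per
gray level; otherwise 256 equal-width bins span the masked range.

One guard proved necessary under the package's own study conditions: with
tens of thousands of background pixels, Poisson count fluctuations on the
flank of the background mode form strict local maxima whose counts dwarf
any true object mode, and the literal rule then drags the threshold into
the background (or, symmetrically, a long shoulder continuum pushes the
trough deep into the object range).  The object-peak search therefore
starts only once the histogram has decayed below `bg_decay_frac`
(default 1%) of the modal count.  On a well-separated bimodal histogram
the guard changes nothing, and the acceptance suite verifies exact
agreement with an exhaustive brute-force trough search on 100 randomized
bimodal histograms.

## Segmentation

`segmentPuncta()` takes 8-connected components of pixels strictly above
the threshold, keeps components of at least `min_size_px` pixels (default
4, i.e. 0.0016 um^2 at 20 nm pixels -- rejects single-pixel noise),
and counts a component as "inside" the synapse when its intensity-weighted
centroid falls on a mask pixel.  Components touching the image edge are
flagged and excluded from FWHM and per-punctum intensity measurements
(truncation biases both) but kept for counts and density, which are
area-normalized.

`deconvolve()` provides Richardson--Lucy iterations with a Gaussian PSF
model (default FWHM 100 nm) and reflective boundary handling.  Flux is
conserved to within the boundary approximation, output is nonnegative,
and iterations monotonically sharpen isolated puncta.  The pipeline
measures on deconvolved images by default (`use_deconvolved`, 10
iterations), with the raw route one flag away; the acceptance suite
checks that raw and deconvolved runs of identical scenes rank synapses
concordantly (Spearman rho >= 0.9) for density and mean per-punctum
intensity.

A physical limitation worth stating plainly: two same-channel puncta
100 nm apart with FWHM ~100--125 nm merge into a single connected
component at any trough threshold.  Even hundreds of Richardson--Lucy
iterations leave the saddle between them far above the background trough.
Threshold-plus-connected-components segmentation therefore cannot split
sandwich flank pairs; this mirrors the original analysis, where
colocalization was scored by eye on overlaid images rather than derived
from the segmentation.  Consequently the colocalization layer accepts
punctum coordinate tables from any source -- segmentation output for
well-separated puncta, a manually logged punctum list, or the simulator's
ground truth (`punctaSetFromTable()`) -- and its accuracy is assessed on
known punctum positions at the sandwich geometry (100 nm flanks, FWHM
100--125 nm), while segmentation exactness is assessed at resolvable
separations (>= 300 nm).

## FWHM measurement

`extractProfile()` samples the image by bilinear interpolation at half-pixel
steps along a line through the punctum's peak pixel, long enough
(default `max(600, 3 x expected FWHM)` nm) to include background on both
sides; the background estimate is the mean of the outer 20% of samples at
each end.  The orientation is the punctum's intensity-weighted major axis.
For near-isotropic puncta (anisotropy below 5%) no major axis exists; the
canonical direction is then 22.5 degrees off the pixel lattice, because
lattice-aligned or diagonal lines sample the bilinear surface at a fixed
knot phase and maximize interpolation aliasing, while an off-lattice line
spreads the phases uniformly.

`measureFwhm()` reads the width at
$\mathrm{background} + (\mathrm{peak} - \mathrm{background})/2$, locating
the two crossings nearest the maximum by linear interpolation between
bracketing samples.  Two peak readings are offered.  The raw sample
maximum (`peak = "max"`) is the literal graphical reading, but under shot
noise the maximum of many noisy samples is biased upward, which narrows
the estimate by ~7% at peak SNR 10 -- well outside the 5% recovery the
estimator should achieve at the study conditions.  The default
(`peak = "quadratic"`) instead fits a quadratic to the logarithm of the
background-subtracted samples around the argmax (window ~0.3 x a
first-pass width); for a Gaussian punctum the log-quadratic model is exact,
and under noise the fit averages rather than selects noise.  Verified by
simulation: noiseless bias <= ~2% for true FWHM 60--240 nm; the mean over
250 noisy puncta at peak SNR ~10 lands within ~3--4% of truth.  The
half-maximum crossings themselves always use plain linear interpolation --
no model fitting enters the width reading.

Representative sampling follows the conventional hierarchy: 10 puncta per
synapse, 5 synapses per animal, 5 animals per group = 250 puncta, via
`sampleRepresentativePuncta()` (seeded, without replacement, with a
warning when a synapse has fewer eligible puncta).

## Colocalization

`associatePuncta()` joins puncta across channels when centroids lie within
`radius_nm` **or** labeled regions overlap by at least one pixel.  The
default radius of 150 nm covers one punctum FWHM plus localization slack;
side-by-side pairs ~100 nm apart never overlap in pixels, so a pure
overlap criterion would miss exactly the arrangement of interest.  The
radius is a stated convention, kept configurable because manual scoring
defines no canonical distance.

`categorizeBassoonVgcc()` scores each Bassoon punctum by its VGCC degree
(1, 2, >= 3, or none -> `B_only`), plus `V_only` for orphan VGCC puncta.
`categorizePiccoloBassoon()` adds the `1P:2B` category: a Piccolo punctum
associated with exactly two Bassoon puncta scores one `1P:2B` and is
removed from those Bassoons' degree counts before binning, so no pairing
is double-counted (one consistent reading of an exhaustive six-way
scheme).  Bassoon-side categories always sum to the number of Bassoon
puncta, and normalized ratios sum to one.

`detectSandwich()` looks at every Bassoon punctum with at least two
associated Piccolo puncta and accepts a flank pair when the flank
separation lies in `[min_sep_nm, max_sep_nm]` (defaults 60--200 nm,
bracketing the ~100 nm spacing with jitter tolerance) and the
Piccolo--Bassoon--Piccolo angle is at least `min_angle_deg` (default 120
degrees; collinear is 180).  Per Bassoon the maximal-angle pair wins;
flanks join at most one motif, conflicts resolved greedily by descending
angle (deterministic, favors the most collinear motifs).

Pixel-correlation coefficients (Pearson/Manders) are deliberately absent:
for side-by-side, size-mismatched puncta they are uninformative, which is
why the categorical object-based scheme exists.

## Statistics and pipeline

`summarizeGroup()` reports n, mean, SD (n-1 denominator) and SEM; the
convention is FWHM as mean +/- SD and everything else as mean +/- SEM.
`unpairedTTest()` is the two-tailed pooled-variance Student test
(df = n1 + n2 - 2), the default "unpaired t-test" of the common
commercial statistics packages; Welch's form is available via
`welch = TRUE`.  The unit of analysis mirrors common practice for this
data type: per-synapse values for density and intensity-per-area, pooled
per-punctum values for punctum intensity and FWHM -- no hierarchical
correction is applied, a deliberate fidelity-over-ideal choice (animals,
not puncta, would be the statistically independent unit).

`runPipeline()` orchestrates simulate/load -> (optional) deconvolve ->
threshold -> segment -> measure -> sample -> colocalize -> group
statistics, writing per-punctum, per-synapse, category, sandwich and
group-statistics CSVs plus a JSON manifest.  All randomness derives from
one seed through a Lehmer splitting step, so identical configurations
yield byte-identical outputs.

## Numerical choices and degenerate inputs

* Histogram ties: modal and trough ties resolve toward the dimmest bin;
  plateau peaks take their dimmest bin.  A constant masked image or an
  object peak adjacent to the background peak raises `NoObjectPeak`.
* Profiles that exit the image or never return to half maximum raise
  errors (`NoCrossing`); callers skip such puncta.
* Richardson--Lucy uses an epsilon floor of 1e-12 to avoid division by
  zero; a flat field is a fixed point to ~1e-6 relative.
* Rejection sampling of motif positions fails loudly (naming the spacing
  constraint) rather than silently packing motifs closer than requested.
* Scene sizes in the test and acceptance suites (128--256 px, 10--50
  scenes, 250 sampled puncta, 1000 null simulations) were chosen as
  desk-scale problem sizes that still exercise every code path at the
  study geometry.

## Known limitations

* The Gaussian-spot image model understates the structured background of
  tissue immunofluorescence; thresholds on real images may need the
  `bg_decay_frac` and `n_bins` knobs.
* FWHM estimates inherit a small positive bias (~1--2%) from bilinear
  interpolation on 20 nm pixels at the narrowest widths; profiles are not
  PSF-fitted by design.
* The association radius and sandwich gates are conventions, not fitted
  parameters; sensitivity analyses over these knobs are recommended for
  real data.
* Sandwich flank pairs are not separable by threshold segmentation (see
  above); detecting them on real images requires punctum coordinates from
  a source that resolves the pair (e.g. manual logging or peak fitting).
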