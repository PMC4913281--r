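# stedpuncta

Object-based quantification of presynaptic active-zone protein puncta in
dual-color STED microscopy images of neuromuscular junctions (NMJs).

STED microscopy resolves the scaffold proteins Bassoon and Piccolo and the
P/Q-type voltage-gated calcium channel (VGCC) as discrete puncta of roughly
100–125 nm FWHM at 20 nm pixels. Quantifying them means answering, per
synapse: how many puncta, how big, how bright, and how are the two channels
arranged — in particular, how often do two Piccolo puncta ~100 nm apart
flank one Bassoon punctum (the Piccolo–Bassoon–Piccolo "sandwich")? The
package implements that measurement chain for image analysts and synapse
biologists, together with a seeded synthetic-scene generator so every stage
can be validated against exact ground truth without microscope data.

## The measurements

For a channel image $I$ and synapse mask $M$ (the labeled
acetylcholine-receptor cluster):

* **Threshold** — histogram-trough auto-threshold for bright objects: the
  modal gray bin of the masked pixels is the background peak, the
  highest-count strict local maximum on the bright side is the object peak,
  and the threshold is the upper edge of the minimal-count bin between them.
* **Puncta** — 8-connected components above threshold, ≥ 4 px, with
  intensity-weighted centroid inside $M$.
* **FWHM** — a bilinear line profile through the punctum peak along its
  intensity-weighted major axis; width read at
  $b + (\mathrm{peak} - b)/2$ (background $b$ from the profile ends) with
  linearly interpolated crossings.
* **Intensity per area** — $\sum_{\text{punctum px} \in M} I \,/\,
  \mathrm{area}(M)$ (µm²); **intensity per punctum** — mean of a punctum's
  pixels; **density** — puncta count / area.
* **Colocalization** — puncta of two channels associate when centroids lie
  within 150 nm or regions overlap; each Bassoon punctum is scored into the
  five-way (VGCC) or six-way (Piccolo, incl. `1P:2B`) categorical scheme,
  and sandwich motifs are detected by flank-separation (60–200 nm) and
  flank-angle (≥ 120°) gates.
* **Statistics** — mean ± SEM (FWHM: mean ± SD) and two-tailed pooled
  t-tests between groups.

Richardson–Lucy deconvolution (Gaussian PSF model, reflective boundaries)
is available and used by the pipeline before thresholding by default.

## Worked example

```r
library(stedpuncta)

## a 5.12 x 5.12 um scene: 3 sandwiches, 4 colocalized pairs, 3 solitary
sc <- buildScene(list(motifSpec("sandwich",  n = 3, jitter_sd_nm = 10),
                      motifSpec("coloc_pair", n = 4),
                      motifSpec("solitary",  n = 3, channel = "bassoon")),
                 width_px = 256, height_px = 256, seed = 42)
sc
#> SceneSpec: 256 x 256 px at 20 nm/px (5.12 x 5.12 um)
#>   channels: bassoon, piccolo
#>   puncta: 20 (bassoon: 10, piccolo: 10)
#>   background 10, read noise SD 1, seed 42

mask <- realizeMask(sc@mask_spec, 256, 256, 20)
img  <- applyNoise(renderChannel(sc, "bassoon"), 1, 43)
thr  <- autoThresholdLight(img, mask)
thr
#> ThresholdResult: threshold 24.72 (background peak bin 13, trough bin 32,
#>   object peak bin 34 of 256)

ps <- segmentPuncta(img, thr@threshold, mask)
punctaDensity(ps, mask)        # 0.5997505 puncta/um^2
ps <- measurePunctaFwhm(img, ps)
head(punctaTable(ps)[, c("label", "area_px", "mean_intensity", "fwhm_nm")], 3)
#>   label area_px mean_intensity  fwhm_nm
#> 1     1      84       71.85500 114.0530
#> 2     2      93       78.95686 107.3431
#> 3     3      71       65.48755 108.5440
```

All ten generated Bassoon puncta are recovered, and the measured FWHMs sit
in the generated 100–125 nm range. Categorical colocalization runs on any
punctum coordinate table (segmentation output, a manually logged punctum
list, or ground truth):

```r
b <- punctaSetFromTable(subset(punctaTable(sc), channel == "bassoon"), "bassoon")
p <- punctaSetFromTable(subset(punctaTable(sc), channel == "piccolo"), "piccolo")
g <- associatePuncta(b, p, radius_nm = 150)
categorizePiccoloBassoon(g)
#> ColocCategoryTable (piccolo_bassoon):
#>   category count normalized
#> 1    1P:1B     4        0.4   <- the 4 colocalized pairs
#> 2    2P:1B     3        0.3   <- the 3 sandwiches
#> 3  >=3P:1B     0        0.0
#> 4    1P:2B     0        0.0
#> 5   B_only     3        0.3   <- the 3 solitary Bassoon
#> 6   P_only     0        0.0

detectSandwich(p, b, g)
#>   bassoon_id piccolo_id_1 piccolo_id_2 flank_separation_nm flank_angle_deg
#> 1          3            1            2            76.69396        150.3329
#> 2          9            7            8           109.79811        163.9503
```

Two of the three sandwiches pass the geometry gates in this single scene
(10 nm positional jitter bent the third below the 120° angle gate); over
many seeded scenes the detector's recall is ~95% with no false hits among
decoys. `runPipeline(pipelineConfig(...), out_dir)` chains the whole
analysis for multi-group designs and writes per-punctum, per-synapse,
category, sandwich and group-statistics CSVs plus a JSON manifest; a thin
CLI (`exec/azpunct`) wraps simulate/segment/run for shell use.

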