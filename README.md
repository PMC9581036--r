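# smartscan

Event-driven ("intelligent") microscopy for R: a feedback acquisition engine
that finds targets of interest in fast, low-resolution **primary scans** and
drives high-resolution **secondary scans** only at the detected stage
positions — plus a virtual microscope so the whole system runs, and is
tested, without hardware.

## Who this is for

Imaging facilities and labs that need to image rare objects or transient
events efficiently: mitotic cells in an asynchronous culture, nuclei with an
abnormal FISH genotype, micropatterns occupied by exactly one cell, or
mitosis onsets captured live from nuclear-envelope breakdown. Acquiring a
wide field entirely at target resolution is prohibitive; for example, a
region covered by a 10 × 10 primary map at a 3× zoom ratio would need
(10·3)·(10·3) = 900 tiles at secondary resolution, each a 3-channel × 65-z
stack — 175,500 images — and a full micropattern chip would need 20,736
fields of 75-image stacks, 1,555,200 images. Feedback acquisition reduces
this to the handful of positions that matter.

## What is inside

* **Core**: tile-grid geometry with exact pixel↔stage transforms, target
  lists (CSV round trip), greedy score-based deduplication, bilinear
  corner-interpolated focus maps.
* **Image operators**: clipped-disk median and outlier-removal filters,
  clamped subtraction, Otsu and fixed thresholds, Laplacian-of-Gaussian
  filtering with prominence-based minima, 8-connected particle analysis
  with Crofton-perimeter circularity, max projection, tile assembly,
  review montages — each verified against brute-force oracles.
* **Detectors** (a plug-in registry; `registerDetector()` adds your own):
  `metaphase` — condensed-chromatin detection via median / remove-outliers /
  difference / threshold / particles ≥ 12 px;
  `fish` — nucleus segmentation, shape/size exclusion, per-channel LoG spot
  counting, multi-phenotype signature matching;
  `micropattern` — valid-pattern localization and the exactly-one-nucleus
  bounding-box rule;
  `mitosis_live` — frame differencing, nucleus-like particle gating, and
  validation by a LoG nucleus minimum in the previous frame.
* **Engine**: the four acquisition state machines (`tiled_fixed`,
  `block_fixed`, `tiled_live`, `block_live`) with review/capping, live
  3-frame queues, blindness during secondary bursts, and a complete
  `AcquisitionLog`; scan-plan arithmetic (`estimateScanPlan()`,
  `tilesAtSecondaryResolution()`).
* **Protocol**: an LF-delimited `/key:value` text-command dialect, a tile
  file-naming convention, a stability-checked exchange-folder collector,
  and offline replay that reproduces a recorded run's log exactly.
* **Simulator**: seeded synthetic scenes (nuclei, FISH spots, micropattern
  grids, live breakdown events) rendered as multi-channel z-stack tiles
  with exportable ground truth; also usable as an in-process acquisition
  server answering protocol commands.

## Worked example

Build the condensed-chromatin reference scene (200 nuclei on a 10 × 10
tiled map, 5 of them condensed), acquire and assemble the primary map, and
run the detector:

```r
library(smartscan)

fx      <- fixtureSpec("metaphase", seed = 1)
scene   <- buildScene(fx$spec)
backend <- simulatorBackend(scene, fx$config)
res     <- runTiledFixed(fx$config, backend)
as.data.frame(res$targets)
```

```
      x_um      y_um z_um     label    score frame_index block_index
1 872.8718  35.16667    0 metaphase 3237.949           0          NA
2 566.9359 129.34615    0 metaphase 3185.603           0          NA
3 785.9557  18.58861    0 metaphase 3152.709           0          NA
4 579.6098 171.91463    0 metaphase 3048.439           0          NA
5 917.0952 282.17857    0 metaphase 2990.321           0          NA
```

Exactly the five planted condensed nuclei are returned (compare
`groundTruth(scene)`), each as an absolute stage position in micrometers
ready for the secondary scan; the score is the particle's mean intensity in
the difference image, which ranks targets for the review montage and the
target cap.

The command line wraps the same functions
(`system.file("cli", "smartscan.R", package = "smartscan")`):

```sh
Rscript inst/cli/smartscan.R plan 900 3 65
# n_images: 175500
Rscript inst/cli/smartscan.R simulate micropattern /tmp/fx --seed 7
Rscript inst/cli/smartscan.R detect micropattern /tmp/fx --out /tmp/out
# 18 target(s) written to /tmp/out/targets.csv
Rscript inst/cli/smartscan.R replay /tmp/fx --out /tmp/run
```

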