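---
title: "Event-driven intelligent microscopy with smartscan: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven intelligent microscopy with smartscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartscan)
```

# The problem

High-resolution fluorescence microscopy of a wide sample area produces data
volumes and acquisition times that are mostly wasted when the objects of
interest are rare: mitotic cells in an asynchronous culture, nuclei with an
aberrant FISH genotype, micropatterns carrying exactly one cell, or a
nuclear-envelope breakdown that lasts minutes in a multi-hour movie.
`smartscan` reorganizes acquisition into two scans: a fast, low-resolution
**primary scan** whose only job is to make targets detectable, and a
high-resolution **secondary scan** restricted to the detected stage
positions. For live samples the loop is closed in real time: the primary
scan runs periodically, an image-analysis workflow is applied on the fly,
and a hit triggers an immediate fixed-length secondary time-lapse centered
on the event before monitoring resumes.

The package contains the full system: the primitive image operators, four
reference detection workflows, the four acquisition state machines (tiled
map or blocks, fixed or live), a text-command dialect plus exchange-folder
transport toward the acquisition side, offline replay, and a virtual
microscope that renders synthetic samples with exportable ground truth so
that every contract of the system is testable without hardware.

# Geometry

A `TileGrid` binds tile indices to stage coordinates: the grid origin is the
stage position of the **center** of tile (0, 0), tiles are laid side by side
with zero overlap, pixel y grows downward, and the stage axes are aligned
with the pixel axes. Pixel coordinates are 0-based and continuous, so
`px = tileW / 2` is exactly the tile center; `pixelToStage()` and
`stageToPixel()` are mutual inverses to numerical precision (property-tested
to 1e-9 µm on 1000 random positions). Real microscopes may flip an axis;
the `axisFlip` flag exists for a hardware bridge but is deliberately
untested against hardware here. Detections are deduplicated greedily by
descending score with a minimum XY separation — deterministic,
order-independent for distinct scores, and faithful to the intent of
keeping the best candidate per object.

For long primary scans the focus surface is approximated by bilinear
interpolation between z values measured at the four corners of the region
(`focusMapInterpolate()`); per-target autofocus before each secondary stack
is the acquisition software's job and is out of scope.

# Image operators

All operators act on plain numeric matrices in detector units. Neighborhood
filters (median, outlier removal) use a disk structuring element **clipped
to the image bounds** — no reflection — because that convention is trivial
to verify against a brute-force per-pixel oracle, and the suite does exactly
that on random images. `removeOutliers()` follows conditional-median
semantics: a pixel is replaced by its disk median only when it exceeds it by
more than a threshold, which erases compact high-contrast objects while
leaving extended structures untouched; the difference image then isolates
exactly the compact objects. Otsu's threshold is computed by exhaustive
between-class-variance search over a 256-bin histogram spanning the image
range.

The Laplacian-of-Gaussian (`logFilter()`) is the workhorse of blob
detection. Sign convention: the response is the raw Laplacian of the
Gaussian-smoothed image, so **bright** blobs of diameter about
`2·sqrt(2)·sigma` give local **minima**; dark blobs are detected on the
negated image. Minima are called *significant* by **topographic prominence**
(depth below the lowest enclosing saddle), not raw depth, which makes every
count invariant to constant intensity offsets — a property the suite
asserts. `logBlobs()` adds two guards: a reported minimum must also be deep
(response at most `-prominence`), which rejects the background catchment's
own minimum — shallow in value yet prominent because every blob is fenced by
a positive response ring — and minima within `2·sigma` of the border are
dropped where the replicate-edge Laplacian is unreliable.

Particle analysis uses 8-connected components, area gates, and circularity
`4πA/P²` with a Crofton perimeter estimated from intercept counts along four
line directions; Crofton has less raster bias than edge counting, converges
to `2πR` for digital disks, and the documented choice lets oracles agree
with the implementation. Note the usual caveat that circularity of very
small components can exceed 1.

# The four detection workflows

All detectors are deterministic pure functions from images to a target list
and are registered by name (`metaphase`, `fish`, `micropattern`,
`mitosis_live`); custom workflows plug in through `registerDetector()` and
are addressable from the experiment configuration.

**Condensed chromatin (mitotic cells).** Median filter → bright-outlier
removal → clamped difference → non-zero threshold → particles of area ≥ 12
px. The outlier radius must exceed the condensed-chromatin radius but stay
below the interphase nucleus radius, so the difference image keeps only the
compact, bright condensed objects; the score is the particle's mean
difference intensity.

**FISH spot-count phenotypes.** Nuclei are segmented from the DAPI channel
(Otsu, hole filling, distance-transform watershed to split touching pairs —
the splitting method is not dictated by the underlying protocol, so the
standard, oracle-testable choice was made), then filtered by area and
circularity (the "invalid shape or size" exclusion). Spots per FISH channel
are LoG blob maxima counted inside each nucleus mask. A list of
`fishSignature` predicates (e.g. counts `(1, 0, 1)` for a missing
chromosome) is evaluated per nucleus; the **first** matching signature wins,
making multi-phenotype experiments deterministic with list order as user
priority.

**Single cells on micropatterns.** Valid patterns are segmented in their
label channel (Otsu + closing, area gates), each pattern's square bounding
box is dilated by a margin, and nuclei are counted inside each box as
significant LoG minima of the DAPI map. Only boxes holding exactly one
nucleus become targets, at the box center.

**Mitosis onset (live).** Nuclear-envelope breakdown floods the formerly
tubulin-dark nuclear disk with signal, so the clamped difference of the two
newest frames (newer − older: the physical direction of the signal) lights
up over the nucleus. The difference is median-filtered and thresholded
(Otsu with a documented floor: on an event-free difference image Otsu
splits pure noise, so the threshold is never allowed below
`threshold_floor` intensity units); candidates must resemble a nucleus in
size and shape, and are validated only if a nucleus — a significant LoG
minimum of the negated previous frame — lies inside the candidate's pixel
set. The third queued frame feeds only the optional temporal-persistence
mode (`persistence = TRUE`, off by default), a generic stand-in for
sample-specific false-positive suppression in highly motile cultures.

# Acquisition state machines

Four modes share one backend contract, so the engine runs identically
against the in-process simulator, an exchange folder, or an offline replay.

* `tiled_fixed`: one primary scan, assembled and max-projected per channel,
  one detection call, optional review (a montage of crops plus a selection
  file of accepted 0-based cell indices — the head-less stand-in for
  interactive montage clicking), a cap keeping the top-scoring targets, and
  one secondary acquisition per surviving target with the stage centered on
  it (a literal reading of "centered on the detected target").
* `block_fixed`: blocks analyzed sequentially, targets tagged with their
  block and accumulated, a **single** secondary scan after the last block;
  review defaults off.
* `tiled_live`: periodic primary frames with a 3-frame queue; the detector
  runs only once the queue is full (frames 0 and 1 are never analyzed). On
  a hit, the highest-scoring target — the system is optimized for fast live
  imaging of single targets — triggers exactly L secondary frames, during
  which the engine is **blind**: no detection calls occur between the mode
  switches, an invariant asserted over 50 random schedules. After the burst
  the queue is flushed: the pre-burst frames are stale after the secondary
  dwell and would create difference artifacts; whether to flush was an open
  design point and the choice is explicit and testable.
* `block_live`: round-robin over blocks (the fairest schedule where none is
  prescribed), one 3-frame queue per block, immediate burst on a hit, resume
  at the next block with only the triggering block's queue flushed.

Every decision is appended to an `AcquisitionLog`; the log minus wall-clock
timestamps is the test surface, and an offline replay of a recorded run must
reproduce it identically. Frame pacing is logical (frame index, not wall
clock) so runs are deterministic.

# Protocol and transport

Messages are LF-terminated lines of `/key:value` fields with a fixed command
vocabulary (`startscan`, `stopscan`, `setposition`, `startcycle`,
`stopcycle`, `scanfinished`; positions in µm as decimal text — the unit is a
documented dialect decision that a hardware bridge must confirm). Values
round-trip verbatim. Images travel as TIFF files named
`{exp}_t####_b###_r##_c##_ch##_z###.tif`; the collector polls until every
expected file exists with a size unchanged across two polls, a stability
check that is portable across network shares. The server side is an
in-process object speaking the same line protocol; a TCP loop would carry
the identical contract but tests run without sockets.

# The virtual microscope

The simulator is the package's executable model of the samples:

* nuclei are soft-edged disks (interphase: dim and large; condensed: 3×
  brighter and 0.4× the radius — condensation concentrates the same DNA
  stain), FISH spots are Gaussians placed inside the nuclear disk with a
  minimum mutual distance so counts are well defined, micropatterns are
  uniform disks in their own label channel, and live scenes render tubulin
  as bright cytoplasm with dark nuclear disks that fill with `neb_level`
  intensity from the scheduled breakdown frame on;
* z is modeled as Gaussian defocus attenuation of 2D objects rather than a
  3D point-spread function — the detectors consume maximum-intensity
  projections, so z realism buys nothing;
* a coarse primary image at binning `k` is computed as the block mean of the
  `k`-times finer render, which makes the downsampling-consistency property
  exact by construction; noise (Poisson with configurable gain plus Gaussian
  read noise) is added on the output raster;
* every random choice derives from the scene seed (per-tile noise streams
  are keyed by position, channel, z, and frame), so fixture folders are
  byte-identical across runs with the same seed.

The reference scenes behind the tests use sizes chosen to keep every
planted object unambiguous: 200 nuclei with 5 condensed on a 10×10 map of
100-px tiles at 1 µm/px; 50 FISH nuclei (10 aberrant, signature 1-0-1) on a
4×4 map at 0.5 µm/px with 3 z slices; a 12×12 pattern grid at 40 µm pitch
with occupancy probabilities (0.55, 0.15, 0.30) — about 15% single-cell
patterns; and a live 2×2 map with three breakdowns scheduled at frames 4,
10 and 16, secondary bursts of L = 12, N = 3. Separations (25 µm between
nuclei, 9 µm between pattern co-occupants) are large enough that detection
failures indicate implementation defects, not ambiguity. What passing these
fixtures does **not** show: robustness to focus drift, uneven illumination,
densely touching cells, or photobleaching — real-data parameter tuning
remains the user's task, which is why every gate and scale is an exposed,
documented parameter.

# Numerical choices and degenerate inputs

Plateaus in the minima search are resolved by processing pixels in (value,
row, col) order, so ties are deterministic; an all-constant image reports no
minima (its single catchment has zero prominence). Non-maximum suppression
visits candidates by decreasing prominence with (row, col) tie-break.
Empty target lists short-circuit every state machine into a `no_targets`
run end. Malformed CSVs, file names, and messages fail with errors naming
the offending line, file, or field; an unknown configuration key is reported
with its path into the document. Rejection sampling of object positions
resamples the whole constrained set (not point by point, which can condition
itself into infeasibility) and errors after bounded retries when the
requested density cannot be packed.

# Known limitations

No hardware control is included: the protocol dialect is versioned so a
bridge to a real acquisition system can adapt it, and position units and
axis orientations must be confirmed there. Interleaved parallel secondary
time-lapses are out of scope. The temporal-persistence option is a labeled
generic mechanism, not a reimplementation of any sample-specific filter.
Detector defaults are calibrated to the reference scenes' intensity scales
(16-bit, thousands of counts); 8-bit or differently scaled data need the
thresholds rescaled.

# Problem sizes used in the test suite

The suite renders the reference scenes at the sizes above (maps up to
1000×1000 px), verifies every operator against brute-force oracles on 100
random images up to 16×16, exercises the live state machine over 50 random
seeds, and replays a recorded live run offline. The whole suite and the
acceptance script each complete in a few minutes on a single CPU.
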