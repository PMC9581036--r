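#' Target detection workflows
#'
#' Four built-in detection workflows, each a deterministic pure function from
#' primary-scan images to a [TargetSet-class], registered in a plug-in
#' registry under the names `metaphase`, `fish`, `micropattern` and
#' `mitosis_live`. Custom detectors can be registered at run time and
#' addressed from the experiment configuration by name.
#'
#' @name detectors
NULL

.detectorRegistry <- new.env(parent = emptyenv())

#' Register / list / fetch target detectors
#'
#' A detector entry is a function `fun(frames, grid, params)` where `frames`
#' is a list of [PrimaryMap-class] objects (length 1 for fixed-sample
#' detectors, the 3 most recent frames, newest last, for live ones), plus its
#' documented parameter defaults. Unknown parameter keys are rejected when
#' the detector runs.
#'
#' @param name unique registry name
#' @param fun detector function `fun(frames, grid, params)`
#' @param defaults named list of documented parameter defaults
#' @param overwrite allow replacing an existing entry
#' @return `registerDetector` the name, invisibly; `listDetectors` a character
#'   vector of registered names; `getDetector` the registry entry
#' @export
registerDetector <- function(name, fun, defaults = list(), overwrite = FALSE) {
  if (!overwrite && exists(name, envir = .detectorRegistry, inherits = FALSE))
    stop("registration error: detector '", name, "' is already registered")
  assign(name, list(fun = fun, defaults = defaults), envir = .detectorRegistry)
  invisible(name)
}

#' @rdname registerDetector
#' @export
listDetectors <- function() sort(ls(.detectorRegistry))

#' @rdname registerDetector
#' @export
getDetector <- function(name) {
  if (!exists(name, envir = .detectorRegistry, inherits = FALSE))
    stop("config error: unknown detector '", name, "' (registered: ",
         paste(listDetectors(), collapse = ", "), ")")
  get(name, envir = .detectorRegistry)
}

# merge user params over defaults, rejecting unknown keys
.mergeParams <- function(params, defaults) {
  if (is.null(params)) params <- list()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("config error: unknown detector parameter(s): ",
         paste(unknown, collapse = ", "))
  utils::modifyList(defaults, params)
}

# particle centroids (1-based matrix indices) -> TargetSet in stage coords
.particlesToTargets <- function(parts, grid, map, label, scores) {
  if (!nrow(parts)) return(emptyTargets())
  pos <- t(mapply(function(r, c) mapPixelToStage(grid, c - 0.5, r - 0.5),
                  parts$centroid_row, parts$centroid_col))
  targetSet(x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
            label = label, score = scores,
            frame_index = map@tIndex, block_index = map@blockIndex)
}

.metaphase_defaults <- list(
  channel = "dna",          # DNA / DAPI channel name
  median_radius = 2,        # px, speckle suppression
  outlier_radius = 5,       # px, must exceed the condensed-chromatin radius
  outlier_threshold = 1000, # detector units, contrast of condensed chromatin
  min_area_px = 12,         # survivors must cover at least this many pixels
  max_area_px = Inf,
  min_separation_um = 10)

#' Detect condensed (mitotic) chromatin in a DNA-channel map
#'
#' Mitotic cells show compact, strongly increased DNA fluorescence. The
#' workflow: median filter (B); remove bright outliers (C), which erases the
#' compact condensed nuclei while leaving extended interphase nuclei intact;
#' clamped difference D = B - C isolates exactly the condensed objects;
#' threshold the non-zero pixels; keep 8-connected particles of area at least
#' `min_area_px` (default 12 px). Targets are placed at particle centroids
#' (converted to stage coordinates), scored by the particle's mean intensity
#' in D, and deduplicated at `min_separation_um`.
#'
#' @param map a [PrimaryMap-class] holding the DNA channel
#' @param grid the map's [TileGrid-class]
#' @param params named list overriding `.metaphase_defaults` entries
#' @return a [TargetSet-class]
#' @export
detectMetaphase <- function(map, grid, params = list()) {
  p <- .mergeParams(params, .metaphase_defaults)
  img <- mapChannel(map, p$channel)
  b <- medianFilterDisk(img, p$median_radius)
  cc <- removeOutliers(b, p$outlier_radius, p$outlier_threshold, "bright")
  d <- subtractClamped(b, cc)
  mask <- thresholdNonzero(d)
  parts <- findParticles(mask, minArea = p$min_area_px, maxArea = p$max_area_px,
                         intensity = d)
  tl <- .particlesToTargets(parts, grid, map, "metaphase", parts$mean_intensity)
  dedupTargets(tl, p$min_separation_um)
}

#' FISH spot-count signature
#'
#' A per-channel predicate on FISH spot counts defining one phenotype of
#' interest, e.g. counts `(1, 0, 1)` for a nucleus missing the chromosome
#' carried by channel 2. Channels with `NA` count are unconstrained; at least
#' one channel must be constrained.
#'
#' @param label phenotype label given to matching targets
#' @param counts numeric vector, expected spot count per channel (NA = any)
#' @param ops comparison per channel: `"=="`, `">="` or `"<="`
#' @return a `fishSignature` object
#' @export
fishSignature <- function(label, counts, ops = rep("==", length(counts))) {
  stopifnot(length(ops) == length(counts),
            all(ops %in% c("==", ">=", "<=")))
  if (all(is.na(counts)))
    stop("config error: a FISH signature must constrain at least one channel")
  structure(list(label = label, counts = counts, ops = ops),
            class = "fishSignature")
}

.sigMatches <- function(sig, counts) {
  for (ch in seq_along(sig$counts)) {
    if (is.na(sig$counts[ch])) next
    ok <- switch(sig$ops[ch],
                 "==" = counts[ch] == sig$counts[ch],
                 ">=" = counts[ch] >= sig$counts[ch],
                 "<=" = counts[ch] <= sig$counts[ch])
    if (!ok) return(FALSE)
  }
  TRUE
}

.fish_defaults <- list(
  dapi_channel = "dna",
  fish_channels = NULL,        # default: all channels matching "fish<k>"
  nucleus_min_area_px = 200,
  nucleus_max_area_px = 900,
  nucleus_min_circularity = 0.7,
  watershed_tolerance = 1,     # EBImage watershed tolerance on the distance map
  spot_sigma_px = 1.2,         # LoG scale matched to the FISH spot size
  spot_prominence = 500,       # LoG-response prominence for a significant spot
  spot_min_distance_px = 3,
  min_separation_um = 10)

#' Classify nuclei by their per-channel FISH spot counts
#'
#' Segments nuclei in the DAPI map (Otsu threshold, hole filling, and
#' distance-transform watershed to split touching pairs), excludes nuclei of
#' invalid shape or size (area outside `[min, max]` or circularity below the
#' gate), counts FISH spots per channel inside each retained nucleus as
#' significant Laplacian-of-Gaussian response minima (bright blobs), and
#' labels each nucleus with the FIRST signature (list order = user priority)
#' whose per-channel predicates all hold. Nuclei matching no signature are
#' ignored. Supports multiple phenotypes in one pass.
#'
#' @param map a [PrimaryMap-class] with the DAPI channel and the FISH channels
#' @param grid the map's [TileGrid-class]
#' @param signatures list of [fishSignature()] objects, highest priority first
#' @param params named list overriding `.fish_defaults`
#' @return a [TargetSet-class] of classified nuclei
#' @export
detectFishPhenotypes <- function(map, grid, signatures, params = list()) {
  p <- .mergeParams(params, .fish_defaults)
  stopifnot(length(signatures) >= 1)
  dapi <- mapChannel(map, p$dapi_channel)
  fishCh <- p$fish_channels
  if (is.null(fishCh))
    fishCh <- grep("^fish[0-9]+$", channelNames(map), value = TRUE)
  if (!length(fishCh)) stop("config error: no FISH channels in map")
  for (sig in signatures)
    if (length(sig$counts) != length(fishCh))
      stop("config error: signature '", sig$label, "' constrains ",
           length(sig$counts), " channels but the map has ", length(fishCh))

  mask <- thresholdGlobal(dapi, "otsu")
  mask <- EBImage::fillHull(mask * 1) > 0
  wl <- EBImage::watershed(EBImage::distmap(mask), tolerance = p$watershed_tolerance)
  labels <- matrix(as.integer(wl), nrow(mask), ncol(mask))

  nlab <- max(labels)
  if (nlab == 0L) return(emptyTargets())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  area <- tabulate(lab, nbins = nlab)
  ri <- (idx - 1L) %% nrow(labels) + 1L
  ci <- (idx - 1L) %/% nrow(labels) + 1L
  crow <- as.numeric(rowsum(ri, lab)) / area
  ccol <- as.numeric(rowsum(ci, lab)) / area
  circ <- 4 * pi * area / croftonPerimeter(labels)^2
  valid <- area >= p$nucleus_min_area_px & area <= p$nucleus_max_area_px &
           circ >= p$nucleus_min_circularity

  # per-channel spot counts per nucleus label
  counts <- matrix(0L, nlab, length(fishCh))
  for (k in seq_along(fishCh)) {
    blobs <- logBlobs(mapChannel(map, fishCh[k]), p$spot_sigma_px,
                      p$spot_prominence, p$spot_min_distance_px)
    if (nrow(blobs)) {
      owner <- labels[cbind(blobs$row, blobs$col)]
      tab <- tabulate(owner[owner > 0L], nbins = nlab)
      counts[, k] <- tab
    }
  }
  keep <- integer(0); labs <- character(0)
  for (l in which(valid)) {
    for (sig in signatures) {
      if (.sigMatches(sig, counts[l, ])) {
        keep <- c(keep, l); labs <- c(labs, sig$label); break
      }
    }
  }
  if (!length(keep)) return(emptyTargets())
  pos <- t(mapply(function(r, c) mapPixelToStage(grid, c - 0.5, r - 0.5),
                  crow[keep], ccol[keep]))
  tl <- targetSet(x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                  label = labs, score = area[keep],
                  frame_index = map@tIndex, block_index = map@blockIndex)
  dedupTargets(tl, p$min_separation_um)
}

.micropattern_defaults <- list(
  pattern_channel = "pattern",
  dapi_channel = "dna",
  pattern_min_area_px = 120,   # "valid pattern" area gate, px
  pattern_max_area_px = 500,
  closing_radius_px = 2,       # morphological closing of the pattern mask
  box_margin_px = 4,           # dilation of the pattern bounding box
  nucleus_diameter_px = 8,     # expected nucleus diameter for the LoG scale
  nucleus_prominence = 100,    # significance gate on LoG minima
  nucleus_min_distance_px = 4)

#' Select micropatterns occupied by exactly one cell
#'
#' Localizes valid micropatterns in their fluorescent label channel (Otsu
#' threshold plus morphological closing, components within the pattern area
#' gates), takes the square bounding box of each valid pattern dilated by a
#' margin, counts nuclei inside each box as significant intensity minima of
#' the Laplacian-of-Gaussian-filtered DAPI map (bright nuclei give response
#' minima; prominence-based significance makes the count invariant to any
#' constant intensity offset), and emits one target at the center of every
#' box holding exactly one nucleus, scored by that minimum's prominence.
#'
#' @param map a [PrimaryMap-class] with the pattern and DAPI channels
#' @param grid the map's [TileGrid-class]
#' @param params named list overriding `.micropattern_defaults`
#' @return a [TargetSet-class] of single-occupancy pattern centers
#' @export
detectIsolatedOnPattern <- function(map, grid, params = list()) {
  p <- .mergeParams(params, .micropattern_defaults)
  pat <- mapChannel(map, p$pattern_channel)
  dapi <- mapChannel(map, p$dapi_channel)
  mask <- thresholdGlobal(pat, "otsu")
  if (p$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * p$closing_radius_px + 1, "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0
  }
  parts <- findParticles(mask, minArea = p$pattern_min_area_px,
                         maxArea = p$pattern_max_area_px)
  if (!nrow(parts)) return(emptyTargets())
  labels <- attr(parts, "labels")

  sigma <- p$nucleus_diameter_px / (2 * sqrt(2))
  minima <- logBlobs(dapi, sigma, p$nucleus_prominence, p$nucleus_min_distance_px)

  out <- emptyTargets()
  for (i in seq_len(nrow(parts))) {
    pix <- which(labels == parts$label[i])
    pr <- (pix - 1L) %% nrow(labels) + 1L
    pc <- (pix - 1L) %/% nrow(labels) + 1L
    # square bounding box, dilated by the margin
    side <- max(max(pr) - min(pr), max(pc) - min(pc)) + 1L + 2L * p$box_margin_px
    cy <- (min(pr) + max(pr)) / 2; cx <- (min(pc) + max(pc)) / 2
    r0 <- cy - side / 2; r1 <- cy + side / 2
    c0 <- cx - side / 2; c1 <- cx + side / 2
    inbox <- minima$row >= r0 & minima$row <= r1 &
             minima$col >= c0 & minima$col <= c1
    if (sum(inbox) == 1L) {
      pos <- mapPixelToStage(grid, cx - 0.5, cy - 0.5)
      out <- bindTargets(out, targetSet(
        x_um = pos[1], y_um = pos[2], z_um = pos[3],
        label = "isolated_cell", score = minima$prominence[inbox],
        frame_index = map@tIndex, block_index = map@blockIndex))
    }
  }
  out
}

.mitosis_defaults <- list(
  channel = "tubulin",
  median_radius = 2,             # px, on the difference image
  threshold_method = "otsu",     # or "fixed" with threshold_value
  threshold_value = NULL,
  threshold_floor = 1000,        # lower bound on the Otsu threshold: on an
                                 # event-free difference image Otsu splits
                                 # pure noise, so a floor in intensity units
                                 # keeps such frames quiet
  min_area_px = 60,              # nucleus-like size gate on candidates
  max_area_px = 500,
  min_circularity = 0.5,         # nucleus-like shape gate
  nucleus_diameter_px = 9,       # LoG scale for the (dark) nuclei; the flat
                                 # disk profile responds best slightly below
                                 # the geometric diameter
  nucleus_prominence = 80,       # significance gate on nucleus minima
  nucleus_min_distance_px = 5,
  persistence = FALSE,           # temporal-persistence confirmation (optional)
  min_separation_um = 10)

#' Detect mitosis onset (nuclear envelope breakdown) in live tubulin frames
#'
#' At nuclear envelope breakdown, tubulin invades the formerly dark nuclear
#' region, so the clamped difference of the two most recent frames (newest
#' minus previous) lights up over the nucleus. The difference is
#' median-filtered, thresholded (Otsu by default, fixed-value override) and
#' analyzed for particles resembling a nucleus in size and shape; a candidate
#' is validated as a detected mitosis only if a nucleus — a significant
#' minimum of the (negated) Laplacian-of-Gaussian response of the PREVIOUS
#' frame, where nuclei are tubulin-dark blobs — falls inside its pixel set.
#' With `persistence = TRUE` a candidate must additionally overlap a
#' candidate region from the preceding frame pair (computed from the oldest
#' of the three queued frames); this generic temporal-persistence option is a
#' stand-in for sample-specific false-positive suppression and is OFF by
#' default.
#'
#' @param frames list of exactly 3 [PrimaryMap-class] objects, newest LAST
#' @param grid the [TileGrid-class] of the frames
#' @param params named list overriding `.mitosis_defaults`
#' @return a [TargetSet-class] of confirmed mitosis onsets
#' @export
detectMitosisOnset <- function(frames, grid, params = list()) {
  if (length(frames) != 3L)
    stop("parameter error: exactly 3 frames required (newest last), got ",
         length(frames))
  p <- .mergeParams(params, .mitosis_defaults)
  f1 <- mapChannel(frames[[1]], p$channel)
  f2 <- mapChannel(frames[[2]], p$channel)
  f3 <- mapChannel(frames[[3]], p$channel)

  candParticles <- function(newer, older) {
    diff <- subtractClamped(newer, older)
    med <- medianFilterDisk(diff, p$median_radius)
    if (max(med) <= 0) return(NULL)
    mask <- if (p$threshold_method == "otsu") {
      thr <- max(otsuThreshold(med), p$threshold_floor)
      med > thr
    } else thresholdGlobal(med, p$threshold_method, p$threshold_value)
    list(parts = findParticles(mask, minArea = p$min_area_px,
                               maxArea = p$max_area_px,
                               minCircularity = p$min_circularity,
                               intensity = diff))
  }
  cur <- candParticles(f3, f2)
  if (is.null(cur) || !nrow(cur$parts)) return(emptyTargets())
  parts <- cur$parts
  labels <- attr(parts, "labels")

  # nuclei in the previous frame: dark blobs -> minima of the negated LoG
  sigma <- p$nucleus_diameter_px / (2 * sqrt(2))
  nucMin <- logBlobs(f2, sigma, p$nucleus_prominence,
                     p$nucleus_min_distance_px, dark = TRUE)

  confirmed <- logical(nrow(parts))
  if (nrow(nucMin)) {
    owner <- labels[cbind(nucMin$row, nucMin$col)]
    confirmed <- parts$label %in% owner[owner > 0L]
  }
  if (p$persistence && any(confirmed)) {
    prev <- candParticles(f2, f1)
    if (is.null(prev) || !nrow(prev$parts)) {
      confirmed[] <- FALSE
    } else {
      prevLab <- attr(prev$parts, "labels")
      prevMask <- matrix(prevLab %in% prev$parts$label, nrow(prevLab))
      for (i in which(confirmed)) {
        pix <- which(labels == parts$label[i])
        confirmed[i] <- any(prevMask[pix])
      }
    }
  }
  parts <- parts[confirmed, , drop = FALSE]
  tl <- .particlesToTargets(parts, grid, frames[[3]], "mitosis_onset",
                            parts$mean_intensity)
  dedupTargets(tl, p$min_separation_um)
}

# built-in registry entries: uniform fun(frames, grid, params) signature
.registerBuiltins <- function() {
  registerDetector("metaphase", function(frames, grid, params)
    detectMetaphase(frames[[length(frames)]], grid, params),
    defaults = .metaphase_defaults, overwrite = TRUE)
  registerDetector("fish", function(frames, grid, params) {
    sigs <- params$signatures
    params$signatures <- NULL
    detectFishPhenotypes(frames[[length(frames)]], grid, sigs, params)
  }, defaults = c(.fish_defaults, list(signatures = NULL)), overwrite = TRUE)
  registerDetector("micropattern", function(frames, grid, params)
    detectIsolatedOnPattern(frames[[length(frames)]], grid, params),
    defaults = .micropattern_defaults, overwrite = TRUE)
  registerDetector("mitosis_live", function(frames, grid, params)
    detectMitosisOnset(frames, grid, params),
    defaults = .mitosis_defaults, overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  .registerBuiltins()
}
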