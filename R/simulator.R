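#' Specification of a synthetic sample for the virtual microscope
#'
#' Describes the object populations, optics and noise of a synthetic scene.
#' All randomness is fixed by `seed`. Intensities are in detector units on
#' the `[0, 2^bitDepth - 1]` scale; positions and sizes in micrometers.
#'
#' @param field numeric length-4 `c(xmin, xmax, ymin, ymax)` stage bounds of
#'   the sample field, micrometers
#' @param bitDepth 8 or 16
#' @param background background level, detector units
#' @param seed integer seed fixing every random choice of the scene
#' @param nuclei NULL or list: `n` count; `radius_um`; `intensity`;
#'   `n_condensed` exact condensed count or `condensed_fraction` per-nucleus
#'   probability; `condensed_ratio` (> 1) intensity ratio of condensed over
#'   interphase; `condensed_radius_factor`; `min_separation_um` center-center
#'   rejection-sampling distance; `edge_margin_um`
#' @param fish NULL or list: `n_channels`; `normal_counts` per-channel spot
#'   counts of the majority population; `aberrant_counts`; `n_aberrant` exact
#'   count of aberrant nuclei; `spot_intensity`; `spot_sigma_um`;
#'   `min_spot_separation_um`
#' @param micropattern NULL or list: `n_rows`, `n_cols`, `pitch_um`,
#'   `origin_um` center of pattern (0,0); `radius_um` pattern radius;
#'   `intensity`; `occupancy_probs` probabilities of 0/1/2 nuclei per pattern;
#'   `occupant_radius_um`, `occupant_intensity`, `occupant_jitter_um`,
#'   `occupant_min_separation_um`
#' @param live NULL or list: `n_frames`; `brownian_sigma_um` per-frame RMS
#'   step of nucleus motion; `tubulin_bg` cytoplasm level of the tubulin
#'   channel; `nucleus_level` tubulin level inside the (dark) nucleus;
#'   `neb_level` tubulin level filling the nuclear disk after envelope
#'   breakdown; `neb_events` data.frame with columns `nucleus` (1-based id)
#'   and `onset` (frame index at which breakdown occurs)
#' @param optics list: `psf_sigma_um` lateral blur of object edges;
#'   `z_sigma_um` Gaussian defocus attenuation scale along z
#' @param noise list: `read_sigma` Gaussian read noise (detector units);
#'   `poisson` logical; `gain` photons per detector unit for Poisson noise
#' @return a validated spec list of class `smartscanSampleSpec`
#' @export
sampleSpec <- function(field = c(-50, 450, -50, 450), bitDepth = 16L,
                       background = 200, seed = 1L,
                       nuclei = NULL, fish = NULL, micropattern = NULL,
                       live = NULL,
                       optics = list(psf_sigma_um = 1, z_sigma_um = 2),
                       noise = list(read_sigma = 0, poisson = FALSE, gain = 0.1)) {
  stopifnot(length(field) == 4, field[2] > field[1], field[4] > field[3],
            bitDepth %in% c(8L, 16L))
  nuclei <- .fillDefaults(nuclei, list(
    n = 0L, radius_um = 8, intensity = 3000, n_condensed = NULL,
    condensed_fraction = NULL, condensed_ratio = 3,
    condensed_radius_factor = 0.4, min_separation_um = 25,
    edge_margin_um = 15), "nuclei")
  if (!is.null(nuclei$condensed_ratio) && nuclei$condensed_ratio <= 1)
    stop("condensed_ratio must be > 1")
  if (!is.null(fish))
    fish <- .fillDefaults(fish, list(
      n_channels = 3L, normal_counts = c(1, 1, 1), aberrant_counts = c(1, 0, 1),
      n_aberrant = 0L, spot_intensity = 20000, spot_sigma_um = 0.6,
      min_spot_separation_um = 4), "fish")
  if (!is.null(micropattern))
    micropattern <- .fillDefaults(micropattern, list(
      n_rows = 12L, n_cols = 12L, pitch_um = 40, origin_um = c(0, 0),
      radius_um = 10, intensity = 5000, occupancy_probs = c(0.55, 0.15, 0.30),
      occupant_radius_um = 3, occupant_intensity = 3000,
      occupant_jitter_um = 6.5, occupant_min_separation_um = 9), "micropattern")
  if (!is.null(live))
    live <- .fillDefaults(live, list(
      n_frames = 1L, brownian_sigma_um = 0, tubulin_bg = 3000,
      nucleus_level = 800, neb_level = 6000,
      neb_events = data.frame(nucleus = integer(), onset = integer())), "live")
  optics <- .fillDefaults(optics, list(psf_sigma_um = 1, z_sigma_um = 2), "optics")
  noise <- .fillDefaults(noise, list(read_sigma = 0, poisson = FALSE, gain = 0.1),
                         "noise")
  structure(list(field = field, bitDepth = as.integer(bitDepth),
                 background = background, seed = as.integer(seed),
                 nuclei = nuclei, fish = fish, micropattern = micropattern,
                 live = live, optics = optics, noise = noise),
            class = "smartscanSampleSpec")
}

# merge user values into defaults, rejecting unknown keys
.fillDefaults <- function(x, defaults, where) {
  if (is.null(x)) return(defaults)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("config error: unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  out <- defaults
  for (k in names(x)) out[[k]] <- x[[k]]    # flat merge: values replace whole
  out
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed from a stream of integers, < 2^31
.mixSeed <- function(...) {
  v <- c(...)
  h <- 0
  for (x in v) h <- (h * 69069 + (as.numeric(x) %% 65011)) %% 2147483647
  as.integer(h)
}

# rejection-sample n points in [xmin,xmax]x[ymin,ymax] with min separation
.samplePositions <- function(n, bounds, minSep, maxTries = 200L) {
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      x <- stats::runif(1, bounds[1], bounds[2])
      y <- stats::runif(1, bounds[3], bounds[4])
      if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= minSep^2)) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("generation error: could not place ", n, " objects at separation ",
           minSep, " um after ", maxTries, " tries (density too high)")
  }
  data.frame(x_um = xs, y_um = ys)
}

#' Build a synthetic scene with complete ground truth
#'
#' Samples every object population of the spec with the spec's seeded
#' generator (rejection sampling enforces the minimum separations, erroring
#' after bounded retries when the requested density cannot be packed),
#' precomputes the Brownian trajectories of live scenes, and records one
#' ground-truth row per rendered object.
#'
#' @param spec a [sampleSpec()]
#' @return a [SimScene-class]
#' @export
buildScene <- function(spec) {
  stopifnot(inherits(spec, "smartscanSampleSpec"))
  .withSeed(spec$seed, {
    nuc <- data.frame(x_um = numeric(), y_um = numeric(), radius_um = numeric(),
                      intensity = numeric(), condensed = logical(),
                      kind = character(), pattern = integer(),
                      neb_onset = integer())
    spots <- data.frame(nucleus = integer(), channel = integer(),
                        x_um = numeric(), y_um = numeric())
    pats <- data.frame(x_um = numeric(), y_um = numeric(), radius_um = numeric(),
                       occupancy = integer())
    ns <- spec$nuclei
    if (ns$n > 0L) {
      m <- ns$edge_margin_um
      pos <- .samplePositions(ns$n, spec$field + c(m, -m, m, -m),
                              ns$min_separation_um)
      cond <- rep(FALSE, ns$n)
      if (!is.null(ns$n_condensed) && ns$n_condensed > 0L)
        cond[sample.int(ns$n, ns$n_condensed)] <- TRUE
      else if (!is.null(ns$condensed_fraction))
        cond <- stats::runif(ns$n) < ns$condensed_fraction
      nuc <- data.frame(
        x_um = pos$x_um, y_um = pos$y_um,
        radius_um = ifelse(cond, ns$radius_um * ns$condensed_radius_factor,
                           ns$radius_um),
        intensity = ifelse(cond, ns$intensity * ns$condensed_ratio, ns$intensity),
        condensed = cond,
        kind = ifelse(cond, "condensed", "interphase"),
        pattern = NA_integer_, neb_onset = NA_integer_)
    }
    counts <- NULL
    if (!is.null(spec$fish) && nrow(nuc)) {
      fs <- spec$fish
      counts <- matrix(rep(fs$normal_counts, each = nrow(nuc)),
                       nrow = nrow(nuc))
      if (fs$n_aberrant > 0L) {
        ab <- sample.int(nrow(nuc), fs$n_aberrant)
        counts[ab, ] <- matrix(rep(fs$aberrant_counts, each = length(ab)),
                               nrow = length(ab))
      }
      for (i in seq_len(nrow(nuc))) {
        for (ch in seq_len(fs$n_channels)) {
          k <- counts[i, ch]
          if (k == 0) next
          rmax <- 0.6 * nuc$radius_um[i]
          sx <- numeric(0); sy <- numeric(0)
          for (s in seq_len(k)) {
            for (try in 1:200) {
              a <- stats::runif(1, 0, 2 * pi); r <- rmax * sqrt(stats::runif(1))
              px <- nuc$x_um[i] + r * cos(a); py <- nuc$y_um[i] + r * sin(a)
              if (!length(sx) ||
                  all((sx - px)^2 + (sy - py)^2 >= fs$min_spot_separation_um^2)) {
                sx <- c(sx, px); sy <- c(sy, py); break
              }
              if (try == 200)
                stop("generation error: cannot place FISH spots at separation ",
                     fs$min_spot_separation_um, " um")
            }
          }
          spots <- rbind(spots, data.frame(nucleus = i, channel = ch,
                                           x_um = sx, y_um = sy))
        }
      }
    }
    if (!is.null(spec$micropattern)) {
      mp <- spec$micropattern
      gx <- mp$origin_um[1] + (seq_len(mp$n_cols) - 1L) * mp$pitch_um
      gy <- mp$origin_um[2] + (seq_len(mp$n_rows) - 1L) * mp$pitch_um
      occ <- sample(0:2, mp$n_rows * mp$n_cols, replace = TRUE,
                    prob = mp$occupancy_probs)
      pats <- data.frame(x_um = rep(gx, times = mp$n_rows),
                         y_um = rep(gy, each = mp$n_cols),
                         radius_um = mp$radius_um, occupancy = occ)
      for (p in seq_len(nrow(pats))) {
        k <- pats$occupancy[p]
        if (k == 0L) next
        # joint rejection sampling: resample the whole set, not point by
        # point (conditioning on an unlucky first draw can make the
        # separation constraint practically infeasible)
        ox <- oy <- NULL
        for (try in 1:500) {
          px <- pats$x_um[p] + stats::runif(k, -mp$occupant_jitter_um,
                                            mp$occupant_jitter_um)
          py <- pats$y_um[p] + stats::runif(k, -mp$occupant_jitter_um,
                                            mp$occupant_jitter_um)
          ok <- k == 1L ||
            min(stats::dist(cbind(px, py))) >= mp$occupant_min_separation_um
          if (ok) { ox <- px; oy <- py; break }
        }
        if (is.null(ox))
          stop("generation error: cannot place pattern occupants at ",
               "separation ", mp$occupant_min_separation_um, " um")
        nuc <- rbind(nuc, data.frame(
          x_um = ox, y_um = oy, radius_um = mp$occupant_radius_um,
          intensity = mp$occupant_intensity, condensed = FALSE,
          kind = "occupant", pattern = p, neb_onset = NA_integer_))
      }
    }
    nFrames <- 1L
    motion <- array(0, dim = c(max(nrow(nuc), 1L), 1L, 2L))
    if (!is.null(spec$live)) {
      lv <- spec$live
      nFrames <- as.integer(lv$n_frames)
      ev <- lv$neb_events
      if (nrow(ev)) nuc$neb_onset[ev$nucleus] <- as.integer(ev$onset)
      motion <- array(0, dim = c(max(nrow(nuc), 1L), nFrames, 2L))
      if (nrow(nuc) && lv$brownian_sigma_um > 0 && nFrames > 1L) {
        for (i in seq_len(nrow(nuc))) {
          dx <- stats::rnorm(nFrames - 1L, 0, lv$brownian_sigma_um)
          dy <- stats::rnorm(nFrames - 1L, 0, lv$brownian_sigma_um)
          motion[i, -1L, 1L] <- cumsum(dx)
          motion[i, -1L, 2L] <- cumsum(dy)
        }
      }
    }
    truth <- .sceneTruth(nuc, counts, pats, spec)
    new("SimScene", spec = unclass(spec), nuclei = nuc, spots = spots,
        patterns = pats, motion = motion, truth = truth,
        seed = spec$seed, nFrames = nFrames)
  })
}

.sceneTruth <- function(nuc, counts, pats, spec) {
  rows <- list()
  if (nrow(nuc)) {
    df <- data.frame(kind = nuc$kind, x_um = nuc$x_um, y_um = nuc$y_um,
                     z_um = 0, occupancy = NA_integer_,
                     onset_frame = nuc$neb_onset, stringsAsFactors = FALSE)
    if (!is.null(counts)) {
      for (ch in seq_len(ncol(counts)))
        df[[paste0("spots_ch", ch)]] <- c(counts[, ch],
                                          rep(NA, nrow(nuc) - nrow(counts)))
    }
    rows$nuclei <- df
  }
  if (nrow(pats)) {
    pdf <- data.frame(kind = "pattern", x_um = pats$x_um, y_um = pats$y_um,
                      z_um = 0, occupancy = pats$occupancy,
                      onset_frame = NA_integer_, stringsAsFactors = FALSE)
    rows$patterns <- pdf
  }
  if (!length(rows))
    return(data.frame(kind = character(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), occupancy = integer(),
                      onset_frame = integer()))
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) { d[setdiff(cols, names(d))] <- NA; d[cols] })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Optics state of an acquisition
#'
#' @param tileH,tileW output raster size in pixels
#' @param pixelSizeUm output lateral sampling, micrometers per pixel
#' @param supersample integer >= 1: the image is rendered on a `supersample`
#'   times finer raster and block-averaged down, emulating the coarse sampling
#'   of an accelerated primary scan (a primary image at binning `k` equals the
#'   block mean of the corresponding full-sampling image)
#' @param nZ number of z slices
#' @param zStepUm z spacing, micrometers
#' @return an optics list for [renderTile()]
#' @export
opticsState <- function(tileH, tileW, pixelSizeUm, supersample = 1L,
                        nZ = 1L, zStepUm = 1) {
  stopifnot(supersample >= 1L, supersample == as.integer(supersample))
  list(tileH = as.integer(tileH), tileW = as.integer(tileW),
       pixelSizeUm = pixelSizeUm, supersample = as.integer(supersample),
       nZ = as.integer(nZ), zStepUm = zStepUm)
}

# soft-edged disk profile: 1 inside radius r, Gaussian falloff of scale e
.softDisk <- function(d, r, e) exp(-pmax(d - r, 0)^2 / (2 * e^2))

#' Render one image tile of a scene
#'
#' Objects are rendered as 2D profiles (soft-edged disks for nuclei and
#' micropatterns, Gaussians for FISH spots) attenuated by Gaussian z defocus,
#' on a raster `supersample` times finer than the output and block-averaged
#' down; Poisson and Gaussian read noise are then added on the output raster
#' and the image is clamped to the bit depth. Live scenes advance nucleus
#' positions by the precomputed Brownian steps; in the tubulin channel nuclei
#' are dark disks in a bright cytoplasm and, from their breakdown onset frame
#' on, the nuclear disk fills with `neb_level` intensity. Noise is
#' deterministic given scene seed, position and all indices. Positions
#' outside the populated field simply render background plus noise.
#'
#' @param scene a [SimScene-class]
#' @param pos stage position of the TILE CENTER, `c(x_um, y_um)` (z ignored)
#' @param channel one of `"dna"`, `"fish1"`..`"fishN"`, `"pattern"`, `"tubulin"`
#' @param zIndex 0-based z slice index
#' @param tIndex 0-based frame index (live scenes)
#' @param optics an [opticsState()]
#' @return numeric matrix `tileH x tileW` of integer-valued intensities
#' @export
renderTile <- function(scene, pos, channel, zIndex = 0L, tIndex = 0L, optics) {
  spec <- scene@spec
  s <- optics$supersample
  Hf <- optics$tileH * s; Wf <- optics$tileW * s
  pf <- optics$pixelSizeUm / s
  # stage coordinates of fine-pixel centers
  xs <- pos[1] + ((seq_len(Wf) - 0.5) - Wf / 2) * pf
  ys <- pos[2] + ((seq_len(Hf) - 0.5) - Hf / 2) * pf
  dz <- (zIndex - (optics$nZ - 1) / 2) * optics$zStepUm
  zatt <- exp(-dz^2 / (2 * spec$optics$z_sigma_um^2))
  edge <- spec$optics$psf_sigma_um
  bg <- spec$background
  img <- matrix(0, Hf, Wf)

  nuc <- scene@nuclei
  ti <- min(tIndex, scene@nFrames - 1L) + 1L
  if (nrow(nuc)) {
    nx <- nuc$x_um + scene@motion[seq_len(nrow(nuc)), ti, 1L]
    ny <- nuc$y_um + scene@motion[seq_len(nrow(nuc)), ti, 2L]
  }
  addProfile <- function(cx, cy, fun, reach) {
    jr <- which(xs >= cx - reach & xs <= cx + reach)
    ir <- which(ys >= cy - reach & ys <= cy + reach)
    if (!length(jr) || !length(ir)) return()
    d <- sqrt(outer((ys[ir] - cy)^2, (xs[jr] - cx)^2, "+"))
    img[ir, jr] <<- img[ir, jr] + fun(d)
  }
  if (channel == "dna") {
    img <- img + bg
    if (nrow(nuc)) for (i in seq_len(nrow(nuc))) {
      r <- nuc$radius_um[i]; A <- nuc$intensity[i] * zatt
      addProfile(nx[i], ny[i], function(d) A * .softDisk(d, r, edge), r + 4 * edge)
    }
  } else if (grepl("^fish[0-9]+$", channel)) {
    img <- img + bg
    ch <- as.integer(sub("fish", "", channel))
    sp <- scene@spots[scene@spots$channel == ch, , drop = FALSE]
    if (nrow(sp)) {
      fs <- spec$fish
      for (i in seq_len(nrow(sp))) {
        A <- fs$spot_intensity * zatt; sg <- fs$spot_sigma_um
        addProfile(sp$x_um[i], sp$y_um[i],
                   function(d) A * exp(-d^2 / (2 * sg^2)), 5 * sg)
      }
    }
  } else if (channel == "pattern") {
    img <- img + bg
    pats <- scene@patterns
    if (nrow(pats)) for (i in seq_len(nrow(pats))) {
      r <- pats$radius_um[i]; A <- spec$micropattern$intensity * zatt
      addProfile(pats$x_um[i], pats$y_um[i],
                 function(d) A * .softDisk(d, r, edge), r + 4 * edge)
    }
  } else if (channel == "tubulin") {
    if (is.null(spec$live)) stop("config error: scene has no live/tubulin population")
    lv <- spec$live
    img <- img + lv$tubulin_bg
    if (nrow(nuc)) for (i in seq_len(nrow(nuc))) {
      r <- nuc$radius_um[i]
      lev <- if (!is.na(nuc$neb_onset[i]) && tIndex >= nuc$neb_onset[i])
        lv$neb_level else lv$nucleus_level
      delta <- (lev - lv$tubulin_bg) * zatt
      addProfile(nx[i], ny[i], function(d) delta * .softDisk(d, r, edge),
                 r + 4 * edge)
    }
  } else stop("config error: unknown channel '", channel, "'")

  # block-mean down to the output raster
  if (s > 1L) {
    img <- .blockMean(img, s)
  }
  # deterministic noise on the output raster
  chId <- sum(utf8ToInt(channel))
  nz <- spec$noise
  if (nz$poisson || nz$read_sigma > 0) {
    sd <- .mixSeed(scene@seed, tIndex, zIndex, chId,
                   round(pos[1] * 100), round(pos[2] * 100))
    img <- .withSeed(sd, {
      out <- img
      if (nz$poisson) out <- stats::rpois(length(out), pmax(out, 0) * nz$gain) / nz$gain
      if (nz$read_sigma > 0) out <- out + stats::rnorm(length(out), 0, nz$read_sigma)
      matrix(out, nrow(img), ncol(img))
    })
  }
  pmin(pmax(round(img), 0), 2^spec$bitDepth - 1)
}

# mean over s x s blocks
.blockMean <- function(img, s) {
  nr <- nrow(img) / s; nc <- ncol(img) / s
  # sum rows within blocks, then cols
  rs <- rowsum(img, rep(seq_len(nr), each = s))
  cs <- t(rowsum(t(rs), rep(seq_len(nc), each = s)))
  cs / (s * s)
}

#' Export a scene's ground truth to CSV
#' @param scene a [SimScene-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
saveGroundTruth <- function(scene, path) {
  utils::write.csv(scene@truth, path, row.names = FALSE)
  invisible(path)
}
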