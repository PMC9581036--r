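#' Experiment configuration
#'
#' Validates and completes an experiment description. Unknown keys anywhere
#' in the document are rejected with the offending key named by its path.
#'
#' @param config named list, typically from [loadConfig()]
#' @return validated config list of class `smartscanConfig`, defaults applied
#' @export
experimentConfig <- function(config) {
  top <- list(
    mode = NULL, experiment = "exp", grid = NULL, blocks = NULL,
    channels = NULL, primary = list(), secondary = list(),
    detector = list(), max_events = 1L, max_primary_frames = 100L,
    target_cap = Inf, review = list(), min_separation_um = 10,
    seed = 1L, exchange_folder = NULL)
  cfg <- .validateKeys(config, top, "")
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("tiled_fixed", "tiled_live", "block_fixed", "block_live"))
    stop("config error at mode: must be one of tiled_fixed, tiled_live, ",
         "block_fixed, block_live")
  live <- grepl("live$", cfg$mode)
  tiled <- grepl("^tiled", cfg$mode)
  cfg$primary <- .validateKeys(cfg$primary,
    list(n_z = 1L, z_step_um = 1, supersample = 1L), "primary")
  cfg$secondary <- .validateKeys(cfg$secondary,
    list(n_timepoints = if (live) NULL else 1L, interval_s = 0,
         channels = NULL, n_z = 1L), "secondary")
  if (live && is.null(cfg$secondary$n_timepoints))
    stop("config error at secondary.n_timepoints: live modes require the ",
         "secondary time-lapse length L")
  if (cfg$secondary$n_timepoints < 1L)
    stop("config error at secondary.n_timepoints: must be >= 1")
  if (cfg$max_events < 1L)
    stop("config error at max_events: must be >= 1")
  cfg$detector <- .validateKeys(cfg$detector,
    list(name = NULL, params = list()), "detector")
  if (is.null(cfg$detector$name))
    stop("config error at detector.name: a detector must be named")
  cfg$review <- .validateKeys(cfg$review,
    list(enabled = !live && cfg$mode == "tiled_fixed", selection_file = NULL,
         montage_file = NULL, montage_box_px = 32L, montage_cols = 8L),
    "review")
  if (tiled) {
    if (is.null(cfg$grid)) stop("config error at grid: tiled modes need one grid")
    cfg$grid <- .asTileGrid(cfg$grid)
  } else {
    if (is.null(cfg$blocks) || !length(cfg$blocks))
      stop("config error at blocks: block modes need at least one block")
    cfg$blocks <- lapply(cfg$blocks, .asTileGrid)
  }
  if (is.null(cfg$channels) || !length(cfg$channels))
    stop("config error at channels: at least one channel required")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "smartscanConfig")
}

.validateKeys <- function(x, template, path) {
  if (is.null(x)) x <- list()
  unknown <- setdiff(names(x), names(template))
  if (length(unknown))
    stop("config error at ", if (nzchar(path)) paste0(path, ".") else "",
         unknown[1], ": unknown key")
  out <- template
  for (k in names(x)) out[k] <- list(x[[k]])
  out
}

.asTileGrid <- function(g) {
  if (is(g, "TileGrid")) return(g)
  g <- .validateKeys(g, list(origin = c(0, 0, 0), n_rows = NULL, n_cols = NULL,
                             tile_h_px = NULL, tile_w_px = NULL,
                             pixel_size_um = NULL, order = "row-major"), "grid")
  TileGrid(unlist(g$origin), g$n_rows, g$n_cols, g$tile_h_px, g$tile_w_px,
           g$pixel_size_um, g$order)
}

# ---- acquisition log -------------------------------------------------------

.newLog <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}

.logEvent <- function(log, event, t_index = NA, block_index = NA,
                      n_targets = NA, target_id = NA, k = NA, of_l = NA,
                      to = NA, reason = NA) {
  log$rows[[length(log$rows) + 1L]] <- data.frame(
    event = event, t_index = as.integer(t_index),
    block_index = as.integer(block_index), n_targets = as.integer(n_targets),
    target_id = as.integer(target_id), k = as.integer(k),
    of_l = as.integer(of_l), to = as.character(to),
    reason = as.character(reason),
    wall_time = as.numeric(Sys.time()), stringsAsFactors = FALSE)
  invisible(log)
}

.finishLog <- function(log) {
  ev <- if (length(log$rows)) do.call(rbind, log$rows) else .log_cols()
  new("AcquisitionLog", events = ev)
}

#' Write / read an AcquisitionLog as line-delimited JSON
#' @param log an [AcquisitionLog-class]
#' @param path file path
#' @return `writeLog`: `path` invisibly; `readLog`: an [AcquisitionLog-class]
#' @export
writeLog <- function(log, path) {
  ev <- logEvents(log)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ev)))
    writeLines(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  invisible(path)
}

#' @rdname writeLog
#' @export
readLog <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  ev <- if (length(rows)) do.call(rbind, rows) else .log_cols()
  proto <- .log_cols()
  for (k in names(proto))                      # canonical column types
    ev[[k]] <- as(ev[[k]], class(proto[[k]]))
  new("AcquisitionLog", events = ev[names(proto)])
}

#' Strip volatile fields from a log for replay comparison
#' @param log an [AcquisitionLog-class]
#' @return the events data.frame without the `wall_time` column
#' @export
logSignature <- function(log) {
  ev <- logEvents(log)
  ev[, setdiff(names(ev), "wall_time"), drop = FALSE]
}

# ---- shared engine steps ---------------------------------------------------

# acquire one primary frame through the backend and assemble per-channel maps
.acquireFrame <- function(backend, block, t, config, log) {
  .logEvent(log, "primary_frame_start", t_index = t, block_index = block)
  raw <- backend$primary(block, t)
  grid <- raw$grid
  maps <- lapply(config$channels, function(ch) {
    proj <- lapply(raw$tiles, function(cell) maxProject(cell[[ch]]))
    assembleTiles(proj, grid)
  })
  names(maps) <- config$channels
  .logEvent(log, "primary_frame_end", t_index = t, block_index = block)
  PrimaryMap(maps, grid, tIndex = t,
             blockIndex = if (is.na(block)) NA_integer_ else as.integer(block))
}

.runDetector <- function(det, frames, grid, config, log) {
  params <- .mergeParams(config$detector$params, det$defaults)
  tl <- det$fun(frames, grid, params)
  .logEvent(log, "detection_call",
            t_index = frames[[length(frames)]]@tIndex,
            block_index = frames[[length(frames)]]@blockIndex,
            n_targets = length(tl))
  tl
}

# cap rule: keep the top-scoring `cap` targets, ties by detection order
.capTargets <- function(targets, cap) {
  if (!is.finite(cap) || length(targets) <= cap) return(targets)
  ord <- order(-targetScores(targets))
  targets[sort(ord[seq_len(cap)])]
}

#' Apply a head-less review selection to a target list
#'
#' The review montage assigns each target a montage cell; the selection file
#' lists the accepted 0-based cell indices, one per line. An absent file
#' accepts every target; an out-of-range index is a selection error.
#'
#' @param targets the [TargetSet-class] under review
#' @param indexMap the `index` data.frame from [makeMontage()]
#' @param selectionFile path to the selection file (may not exist)
#' @return the accepted subset, in original order
#' @export
applyReview <- function(targets, indexMap, selectionFile) {
  if (is.null(selectionFile) || !file.exists(selectionFile)) return(targets)
  lines <- readLines(selectionFile)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cells <- suppressWarnings(as.integer(lines))
  if (any(is.na(cells)))
    stop("selection error: non-numeric entry in ", selectionFile)
  bad <- setdiff(cells, indexMap$cell)
  if (length(bad))
    stop("selection error: montage cell index ", bad[1], " out of range")
  sel <- sort(indexMap$target[match(cells, indexMap$cell)])
  targets[sel]
}

# secondary scan of a fixed-sample target list: each target acquired once,
# stage centered on the target
.secondaryFixed <- function(targets, backend, config, log) {
  .logEvent(log, "mode_switch", to = "to_secondary")
  df <- as.data.frame(targets)
  for (i in seq_len(nrow(df))) {
    backend$secondary(df[i, ], 1L, df$frame_index[i], config)
    .logEvent(log, "secondary_frame", target_id = i, k = 1L, of_l = 1L)
  }
  .logEvent(log, "mode_switch", to = "to_primary")
}

# secondary burst of a live target: exactly L frames centered on the target
.secondaryBurst <- function(target, targetId, backend, config, t, log) {
  L <- config$secondary$n_timepoints
  .logEvent(log, "mode_switch", t_index = t, to = "to_secondary")
  for (k in seq_len(L)) {
    backend$secondary(target, k, t, config)
    .logEvent(log, "secondary_frame", t_index = t, target_id = targetId,
              k = k, of_l = L)
  }
  .logEvent(log, "mode_switch", t_index = t, to = "to_primary")
}

# ---- the four acquisition state machines -----------------------------------

#' Run a fixed-sample tiled-map experiment
#'
#' One primary scan, assembled and max-projected per channel, is handed to
#' the detector once. The detection may be refined through the review
#' montage/selection file, is capped to `target_cap` (top score first, ties
#' by detection order), and every surviving target is acquired once by the
#' secondary scan with the stage centered on it.
#'
#' @param config a `smartscanConfig` (mode `tiled_fixed`)
#' @param backend an acquisition backend ([simulatorBackend()] or
#'   [replaySource()])
#' @return list with `targets` (the acquired [TargetSet-class]) and `log`
#'   (the [AcquisitionLog-class])
#' @export
runTiledFixed <- function(config, backend) {
  stopifnot(config$mode == "tiled_fixed")
  det <- getDetector(config$detector$name)
  log <- .newLog()
  map <- .acquireFrame(backend, NA_integer_, 0L, config, log)
  tl <- .runDetector(det, list(map), map@grid, config, log)
  if (length(tl) == 0L) {
    .logEvent(log, "run_end", reason = "no_targets")
    return(list(targets = tl, log = .finishLog(log)))
  }
  if (isTRUE(config$review$enabled) &&
      (!is.null(config$review$selection_file) ||
       !is.null(config$review$montage_file))) {
    mont <- makeMontage(mapChannel(map, config$channels[1]), tl, map@grid,
                        config$review$montage_box_px, config$review$montage_cols)
    if (!is.null(config$review$montage_file))
      writeImageTiff(mont$montage, config$review$montage_file)
    if (!is.null(config$review$selection_file))
      tl <- applyReview(tl, mont$index, config$review$selection_file)
  }
  tl <- .capTargets(tl, config$target_cap)
  if (length(tl)) .secondaryFixed(tl, backend, config, log)
  .logEvent(log, "run_end", reason = "completed")
  list(targets = tl, log = .finishLog(log))
}

#' Run a fixed-sample block-mode experiment
#'
#' Blocks are scanned and analyzed sequentially; per-block targets are tagged
#' with their block index and accumulated; after the LAST block, the pooled
#' list is deduplicated, capped, and acquired in a single secondary scan.
#' Review is off by default in block mode (typically far too many targets to
#' inspect).
#'
#' @inheritParams runTiledFixed
#' @return list with `targets` and `log`
#' @export
runBlockFixed <- function(config, backend) {
  stopifnot(config$mode == "block_fixed")
  det <- getDetector(config$detector$name)
  log <- .newLog()
  acc <- emptyTargets()
  for (b in seq_along(config$blocks) - 1L) {
    map <- .acquireFrame(backend, b, 0L, config, log)
    tl <- .runDetector(det, list(map), map@grid, config, log)
    acc <- bindTargets(acc, tl)
  }
  acc <- dedupTargets(acc, config$min_separation_um)
  acc <- .capTargets(acc, config$target_cap)
  if (length(acc)) .secondaryFixed(acc, backend, config, log)
  .logEvent(log, "run_end",
            reason = if (length(acc)) "completed" else "no_targets")
  list(targets = acc, log = .finishLog(log))
}

#' Run a live tiled-map experiment
#'
#' Primary frames are acquired periodically and the three most recent frames
#' are queued; the detector is invoked only once the queue is full (frames 0
#' and 1 are never analyzed). On a hit the highest-scoring target triggers an
#' immediate switch to secondary scan — no user validation — and exactly L
#' frames are acquired centered on it; the engine is blind to new events
#' during the burst (no detection calls between the mode switches). After the
#' burst the frame queue is flushed: the pre-burst frames are stale after the
#' secondary dwell and would create difference artifacts. The run ends after
#' `max_events` acquired events or `max_primary_frames` primary frames.
#'
#' @inheritParams runTiledFixed
#' @return list with `targets` (one per acquired event) and `log`
#' @export
runTiledLive <- function(config, backend) {
  stopifnot(config$mode == "tiled_live")
  det <- getDetector(config$detector$name)
  log <- .newLog()
  queue <- list()
  acquired <- emptyTargets()
  nEvents <- 0L
  reason <- "max_primary_frames"
  t <- 0L
  while (t < config$max_primary_frames) {
    if (!backend$hasFrame(t)) { reason <- "frames_exhausted"; break }
    map <- .acquireFrame(backend, NA_integer_, t, config, log)
    queue <- c(queue, list(map))
    if (length(queue) > 3L) queue <- queue[-1L]
    if (length(queue) == 3L) {
      tl <- .runDetector(det, queue, map@grid, config, log)
      if (length(tl) > 0L) {
        best <- tl[which.max(targetScores(tl))]
        nEvents <- nEvents + 1L
        acquired <- bindTargets(acquired, best)
        .secondaryBurst(as.data.frame(best)[1, ], nEvents, backend, config, t, log)
        queue <- list()              # restart the 3-frame fill
        if (nEvents >= config$max_events) { reason <- "max_events"; break }
      }
    }
    t <- t + 1L
  }
  .logEvent(log, "run_end", reason = reason)
  list(targets = acquired, log = .finishLog(log))
}

#' Run a live block-mode experiment
#'
#' Blocks are monitored cyclically (round-robin; the fairest schedule when
#' none is prescribed), each keeping its own 3-frame queue, with a detection
#' call immediately after each block's frame once its queue is full. A hit
#' triggers the secondary burst at once; monitoring resumes at the NEXT
#' block, the triggering block's queue is flushed and all other queues are
#' retained.
#'
#' @inheritParams runTiledFixed
#' @return list with `targets` and `log`
#' @export
runBlockLive <- function(config, backend) {
  stopifnot(config$mode == "block_live")
  det <- getDetector(config$detector$name)
  log <- .newLog()
  nb <- length(config$blocks)
  queues <- rep(list(list()), nb)
  acquired <- emptyTargets()
  nEvents <- 0L
  reason <- "max_primary_frames"
  done <- FALSE
  t <- 0L
  while (t < config$max_primary_frames && !done) {
    for (b in seq_len(nb) - 1L) {
      if (!backend$hasFrame(t)) { reason <- "frames_exhausted"; done <- TRUE; break }
      map <- .acquireFrame(backend, b, t, config, log)
      q <- c(queues[[b + 1L]], list(map))
      if (length(q) > 3L) q <- q[-1L]
      queues[[b + 1L]] <- q
      if (length(q) == 3L) {
        tl <- .runDetector(det, q, map@grid, config, log)
        if (length(tl) > 0L) {
          best <- tl[which.max(targetScores(tl))]
          nEvents <- nEvents + 1L
          acquired <- bindTargets(acquired, best)
          .secondaryBurst(as.data.frame(best)[1, ], nEvents, backend, config, t, log)
          queues[[b + 1L]] <- list()       # only the triggering block's queue
          if (nEvents >= config$max_events) {
            reason <- "max_events"; done <- TRUE; break
          }
        }
      }
    }
    t <- t + 1L
  }
  .logEvent(log, "run_end", reason = reason)
  list(targets = acquired, log = .finishLog(log))
}

#' Run the experiment mode named in the configuration
#' @inheritParams runTiledFixed
#' @return list with `targets` and `log`
#' @export
runExperiment <- function(config, backend) {
  switch(config$mode,
         tiled_fixed = runTiledFixed(config, backend),
         tiled_live = runTiledLive(config, backend),
         block_fixed = runBlockFixed(config, backend),
         block_live = runBlockLive(config, backend))
}

# ---- scan-plan arithmetic --------------------------------------------------

#' Scan-plan data-volume arithmetic
#'
#' How many images (and bytes) a plan acquires: either
#' `n_tiles * n_channels * n_z`, or `n_tiles * images_per_fov` when a
#' per-field-of-view stack size is given directly.
#'
#' @param nTiles number of tiles / fields of view
#' @param nChannels channels per field
#' @param nZ z slices per channel
#' @param imagesPerFov optional images per field of view, overriding
#'   `nChannels * nZ`
#' @param bytesPerImage optional bytes per image
#' @return list with `n_images`, `n_fov`, `bytes` (NA when `bytesPerImage`
#'   is missing)
#' @examples
#' estimateScanPlan(900, 3, 65)$n_images       # 175500
#' estimateScanPlan(20736, imagesPerFov = 75)$n_images  # 1555200
#' @export
estimateScanPlan <- function(nTiles, nChannels = 1, nZ = 1,
                             imagesPerFov = NULL, bytesPerImage = NULL) {
  stopifnot(nTiles >= 0, nChannels >= 0, nZ >= 0)
  nImages <- if (!is.null(imagesPerFov)) nTiles * imagesPerFov
             else nTiles * nChannels * nZ
  list(n_images = nImages, n_fov = nTiles,
       bytes = if (is.null(bytesPerImage)) NA_real_ else nImages * bytesPerImage)
}

#' Tiles needed to cover a primary-scan region at secondary resolution
#'
#' A primary grid of `nRows x nCols` tiles acquired at a linear resolution
#' ratio `k` (secondary pixels are `k` times finer) would need
#' `(nRows*k) * (nCols*k)` tiles at the secondary scan's resolution.
#'
#' @param nRows,nCols primary grid dimensions in tiles
#' @param k integer linear resolution ratio (>= 1)
#' @return tile count at secondary resolution
#' @examples
#' tilesAtSecondaryResolution(10, 10, 3)  # 900
#' @export
tilesAtSecondaryResolution <- function(nRows, nCols, k) {
  stopifnot(k >= 1, k == as.integer(k))
  (nRows * k) * (nCols * k)
}
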