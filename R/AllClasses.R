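#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib smartscan, .registration = TRUE
NULL

#' TileGrid: geometry of a tiled primary scan
#'
#' Binds tile indices (row, col) to absolute stage positions and pixel rasters.
#' The grid origin is the stage position of the CENTER of tile (0, 0); tiles
#' are laid side by side with zero overlap. Pixel coordinates are 0-based
#' continuous, with y increasing downward and the stage axes aligned with the
#' pixel axes (no rotation or mirroring); `axisFlip` is a convention flag for
#' real-microscope bridges and is not exercised by the simulator.
#'
#' @slot originX,originY,originZ stage position of the center of tile (0,0), in micrometers
#' @slot nRows,nCols number of tile rows / columns
#' @slot tileH,tileW tile raster size in pixels
#' @slot pixelSize lateral sampling of the primary scan, micrometers per pixel
#' @slot scanOrder tile visiting order, `"row-major"` or `"serpentine"`
#' @slot axisFlip length-2 logical, flip stage x / y relative to pixel axes
#' @export
setClass("TileGrid",
  representation(originX = "numeric", originY = "numeric", originZ = "numeric",
                 nRows = "integer", nCols = "integer",
                 tileH = "integer", tileW = "integer",
                 pixelSize = "numeric", scanOrder = "character",
                 axisFlip = "logical"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(c(object@originX, object@originY, object@originZ))))
      msg <- c(msg, "grid origin must be finite")
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "nRows and nCols must be >= 1")
    if (object@tileH < 1L || object@tileW < 1L)
      msg <- c(msg, "tile raster size must be >= 1 px")
    if (!isTRUE(object@pixelSize > 0))
      msg <- c(msg, "pixelSize must be > 0")
    if (!object@scanOrder %in% c("row-major", "serpentine"))
      msg <- c(msg, "scanOrder must be 'row-major' or 'serpentine'")
    if (length(msg)) msg else TRUE
  })

#' Construct a TileGrid
#'
#' @param origin numeric length-3 stage position (x, y, z in micrometers) of the
#'   center of tile (0, 0)
#' @param nRows,nCols grid dimensions in tiles
#' @param tileH,tileW tile raster size in pixels
#' @param pixelSize micrometers per pixel of the primary scan raster
#' @param scanOrder `"row-major"` (default) or `"serpentine"`
#' @param axisFlip logical length-2, stage-axis flip flags (untested against hardware)
#' @return a [TileGrid-class] object
#' @examples
#' g <- TileGrid(c(0, 0, 0), nRows = 10, nCols = 10, tileH = 100, tileW = 100,
#'               pixelSize = 1)
#' @export
TileGrid <- function(origin = c(0, 0, 0), nRows, nCols, tileH, tileW,
                     pixelSize, scanOrder = "row-major",
                     axisFlip = c(FALSE, FALSE)) {
  new("TileGrid", originX = as.numeric(origin[1]), originY = as.numeric(origin[2]),
      originZ = as.numeric(origin[3]),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      tileH = as.integer(tileH), tileW = as.integer(tileW),
      pixelSize = as.numeric(pixelSize), scanOrder = scanOrder,
      axisFlip = as.logical(axisFlip))
}

#' @describeIn TileGrid number of tile rows
#' @param x,object a `TileGrid`
#' @export
nRows <- function(x) x@nRows
#' @describeIn TileGrid number of tile columns
#' @export
nCols <- function(x) x@nCols
#' @describeIn TileGrid micrometers per pixel
#' @export
pixelSize <- function(x) x@pixelSize
#' @describeIn TileGrid stage position of the center of tile (0,0) as c(x, y, z)
#' @export
gridOrigin <- function(x) c(x@originX, x@originY, x@originZ)

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d x %d tiles of %d x %d px @ %.4g um/px, origin (%g, %g, %g) um, %s\n",
              object@nRows, object@nCols, object@tileH, object@tileW,
              object@pixelSize, object@originX, object@originY, object@originZ,
              object@scanOrder))
})

.target_cols <- c("x_um", "y_um", "z_um", "label", "score",
                  "frame_index", "block_index")

#' TargetSet: an ordered list of detected targets
#'
#' Each target is a detected object: absolute stage position, phenotype label,
#' detection score, primary-scan frame of detection and block of origin
#' (`NA` outside block mode).
#'
#' @slot targets data.frame with columns `x_um`, `y_um`, `z_um`, `label`,
#'   `score`, `frame_index`, `block_index`
#' @export
setClass("TargetSet", representation(targets = "data.frame"),
  validity = function(object) {
    df <- object@targets
    if (!identical(names(df), .target_cols))
      return(sprintf("targets must have columns: %s", paste(.target_cols, collapse = ", ")))
    if (nrow(df)) {
      if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)) || !all(is.finite(df$z_um)))
        return("target stage positions must be finite")
      if (any(df$score < 0)) return("target scores must be >= 0")
    }
    TRUE
  })

#' Construct a TargetSet
#'
#' @param x_um,y_um,z_um stage coordinates in micrometers
#' @param label phenotype label (recycled)
#' @param score non-negative detection strength
#' @param frame_index primary-scan time index of detection
#' @param block_index block of origin, `NA` when not in block mode
#' @return a [TargetSet-class]
#' @export
targetSet <- function(x_um = numeric(), y_um = numeric(), z_um = 0,
                      label = "target", score = 0, frame_index = 0L,
                      block_index = NA_integer_) {
  n <- length(x_um)
  df <- data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   z_um = rep_len(as.numeric(z_um), n),
                   label = rep_len(as.character(label), n),
                   score = rep_len(as.numeric(score), n),
                   frame_index = rep_len(as.integer(frame_index), n),
                   block_index = rep_len(as.integer(block_index), n),
                   stringsAsFactors = FALSE)
  new("TargetSet", targets = df)
}

#' @describeIn targetSet an empty TargetSet
#' @export
emptyTargets <- function() targetSet()

#' @export
setMethod("length", "TargetSet", function(x) nrow(x@targets))

#' @export
setMethod("as.data.frame", "TargetSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@targets)

#' @export
setMethod("[", "TargetSet", function(x, i, j, ..., drop = TRUE) {
  new("TargetSet", targets = x@targets[i, , drop = FALSE])
})

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet with %d target(s)\n", nrow(object@targets)))
  if (nrow(object@targets)) print(utils::head(object@targets, 10))
})

#' @describeIn targetSet detection scores
#' @param x a `TargetSet`
#' @export
targetScores <- function(x) x@targets$score
#' @describeIn targetSet phenotype labels
#' @export
targetLabels <- function(x) x@targets$label
#' @describeIn targetSet stage positions as a data.frame (x_um, y_um, z_um)
#' @export
targetPositions <- function(x) x@targets[, c("x_um", "y_um", "z_um")]

#' @describeIn targetSet concatenate TargetSets in order
#' @param ... TargetSets
#' @export
bindTargets <- function(...) {
  dfs <- lapply(list(...), function(t) t@targets)
  new("TargetSet", targets = do.call(rbind, c(dfs, list(make.row.names = FALSE))))
}

#' PrimaryMap: an assembled, max-projected primary-scan frame
#'
#' One multi-channel 2D image covering the whole tile grid, together with the
#' geometry needed to convert map pixels back to stage positions, the
#' primary-scan time index and the block of origin.
#'
#' @slot channels named list of numeric matrices, one per channel, equal shapes
#' @slot grid the [TileGrid-class] the map was assembled from
#' @slot tIndex primary-scan time index
#' @slot blockIndex block index (`NA` outside block mode)
#' @export
setClass("PrimaryMap",
  representation(channels = "list", grid = "TileGrid",
                 tIndex = "integer", blockIndex = "integer"),
  validity = function(object) {
    ch <- object@channels
    if (!length(ch)) return("at least one channel required")
    if (is.null(names(ch)) || any(!nzchar(names(ch)))) return("channels must be named")
    dims <- vapply(ch, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all channels must have the same shape")
    TRUE
  })

#' @describeIn PrimaryMap-class construct a PrimaryMap
#' @param channels named list of matrices
#' @param grid a `TileGrid`
#' @param tIndex time index
#' @param blockIndex block index or NA
#' @export
PrimaryMap <- function(channels, grid, tIndex = 0L, blockIndex = NA_integer_) {
  new("PrimaryMap", channels = channels, grid = grid,
      tIndex = as.integer(tIndex), blockIndex = as.integer(blockIndex))
}

#' @describeIn PrimaryMap-class channel names
#' @param x,object a `PrimaryMap`
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn PrimaryMap-class extract one channel image (matrix)
#' @param name channel name
#' @export
mapChannel <- function(x, name) {
  if (!name %in% names(x@channels))
    stop("config error: channel '", name, "' not present in map (has: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
}

setMethod("show", "PrimaryMap", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("PrimaryMap t=%d block=%s: %d x %d px, channels: %s\n",
              object@tIndex, ifelse(is.na(object@blockIndex), "-", object@blockIndex),
              d[1], d[2], paste(names(object@channels), collapse = ", ")))
})

#' AcquisitionLog: ordered record of engine decisions
#'
#' Every acquisition and detection decision made by the engine is appended as
#' one event row. Event types: `primary_frame_start`, `primary_frame_end`,
#' `detection_call`, `mode_switch` (`to` = `to_secondary` / `to_primary`),
#' `secondary_frame` (`target_id`, `k` of `of_l`) and `run_end` (`reason`).
#'
#' @slot events data.frame, one row per event, in chronological order
#' @export
setClass("AcquisitionLog", representation(events = "data.frame"))

.log_cols <- function() {
  data.frame(event = character(), t_index = integer(), block_index = integer(),
             n_targets = integer(), target_id = integer(), k = integer(),
             of_l = integer(), to = character(), reason = character(),
             wall_time = numeric(), stringsAsFactors = FALSE)
}

#' @export
setMethod("as.data.frame", "AcquisitionLog",
          function(x, row.names = NULL, optional = FALSE, ...) x@events)

#' @describeIn AcquisitionLog-class the events data.frame
#' @param x,object an `AcquisitionLog`
#' @export
logEvents <- function(x) x@events

setMethod("show", "AcquisitionLog", function(object) {
  ev <- object@events
  cat(sprintf("AcquisitionLog with %d event(s)\n", nrow(ev)))
  if (nrow(ev)) print(table(ev$event))
})

#' SimScene: a synthetic sample rendered by the virtual microscope
#'
#' Holds the sampled object populations (nuclei, FISH spots, micropatterns),
#' precomputed per-frame Brownian motion for live scenes, the complete ground
#' truth table, and the seed that fixes everything.
#'
#' @slot spec the [sampleSpec()] the scene was built from
#' @slot nuclei data.frame of nuclei (position, radius, intensity, condensed flag, ...)
#' @slot spots data.frame of FISH spots (nucleus id, channel, position)
#' @slot patterns data.frame of micropatterns (position, radius, occupancy)
#' @slot motion numeric array `n_nuclei x n_frames x 2` of cumulative Brownian
#'   displacements (micrometers), or 0-extent array for fixed scenes
#' @slot truth ground-truth data.frame, one row per rendered object
#' @slot seed integer seed the scene was built with
#' @slot nFrames number of live frames supported (1 for fixed scenes)
#' @export
setClass("SimScene",
  representation(spec = "list", nuclei = "data.frame", spots = "data.frame",
                 patterns = "data.frame", motion = "array", truth = "data.frame",
                 seed = "integer", nFrames = "integer"))

#' @describeIn SimScene-class the ground truth table
#' @param x,object a `SimScene`
#' @export
groundTruth <- function(x) x@truth

setMethod("show", "SimScene", function(object) {
  cat(sprintf("SimScene (seed %d): %d nuclei, %d FISH spots, %d patterns, %d frame(s)\n",
              object@seed, nrow(object@nuclei), nrow(object@spots),
              nrow(object@patterns), object@nFrames))
})
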