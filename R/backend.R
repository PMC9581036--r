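#' In-process virtual-microscope acquisition backend
#'
#' Implements the engine's backend contract on top of the simulator, as an
#' alternative to the exchange-folder transport with identical semantics: the
#' engine code is the same against a simulator backend, a folder replay, or a
#' real acquisition bridge. With `recordDir` set, every primary-scan tile is
#' additionally written to the folder under the exchange naming convention,
#' producing a primary-scan folder that can be replayed offline with
#' [replaySource()].
#'
#' Channel names in the experiment config must name simulator channels
#' (`dna`, `fish1`.., `pattern`, `tubulin`).
#'
#' @param scene a [SimScene-class]
#' @param config a `smartscanConfig`
#' @param recordDir optional folder to record primary tiles into
#' @return a backend list with `primary(block, t)`, `secondary(target, k, t,
#'   config)`, `hasFrame(t)`, `nBlocks`, `kind = "simulator"`
#' @export
simulatorBackend <- function(scene, config, recordDir = NULL) {
  if (!is.null(recordDir)) dir.create(recordDir, showWarnings = FALSE,
                                      recursive = TRUE)
  blockGrid <- function(block) {
    if (is.na(block) || is.null(config$blocks)) config$grid
    else config$blocks[[block + 1L]]
  }
  live <- !is.null(scene@spec$live)
  list(
    kind = "simulator",
    nBlocks = if (is.null(config$blocks)) 1L else length(config$blocks),
    hasFrame = function(t) !live || t < scene@nFrames,
    primary = function(block, t) {
      g <- blockGrid(block)
      optics <- opticsState(g@tileH, g@tileW, g@pixelSize,
                            supersample = config$primary$supersample,
                            nZ = config$primary$n_z,
                            zStepUm = config$primary$z_step_um)
      ncell <- g@nRows * g@nCols
      tiles <- vector("list", ncell)
      for (cell in seq_len(ncell)) {
        r <- (cell - 1L) %/% g@nCols
        cc <- (cell - 1L) %% g@nCols
        center <- tileCenter(g, r, cc)
        perch <- stats::setNames(vector("list", length(config$channels)),
                                 config$channels)
        for (ci in seq_along(config$channels)) {
          ch <- config$channels[ci]
          stack <- lapply(seq_len(config$primary$n_z) - 1L, function(z) {
            img <- renderTile(scene, center, ch, zIndex = z, tIndex = t,
                              optics = optics)
            if (!is.null(recordDir))
              writeImageTiff(img, file.path(recordDir, formatTileName(
                config$experiment, t, ifelse(is.na(block), 0L, block),
                r, cc, ci - 1L, z)), scene@spec$bitDepth)
            img
          })
          perch[[ci]] <- stack
        }
        tiles[[cell]] <- perch
      }
      list(grid = g, tiles = tiles)
    },
    secondary = function(target, k, t, config) {
      # full-sampling field centered on the target (z projection not needed:
      # the engine only records the acquisition; the image is returned)
      g <- blockGrid(if (is.null(target$block_index)) NA else target$block_index)
      optics <- opticsState(g@tileH, g@tileW,
                            g@pixelSize / config$primary$supersample,
                            supersample = 1L, nZ = config$secondary$n_z)
      ch <- if (!is.null(config$secondary$channels))
        config$secondary$channels[1] else config$channels[1]
      invisible(renderTile(scene, c(target$x_um, target$y_um), ch,
                           zIndex = 0L, tIndex = t, optics = optics))
    }
  )
}

#' In-process acquisition server speaking the text-command dialect
#'
#' Emulates the acquisition-software side of the client-server architecture:
#' commands arrive as encoded message lines ([encodeMessage()]) and scans are
#' answered by writing TIFF tiles into the exchange folder (named per
#' [formatTileName()]) followed by the scan-finished notification. Malformed
#' commands get a protocol error reply and the server keeps running. The
#' transport is a plain line interface, so it can be driven in-process or
#' bridged over any line-oriented connection.
#'
#' @param scene a [SimScene-class]
#' @param grid the [TileGrid-class] scanned on `startscan`
#' @param channels simulator channel names acquired per tile
#' @param folder exchange folder the tiles are written into
#' @param nZ z slices per channel
#' @param supersample primary-scan binning factor (see [opticsState()])
#' @param experiment experiment id used in the file names
#' @return an environment with `handleLine(line)` returning the reply line,
#'   and fields `tIndex`, `position`
#' @export
camServer <- function(scene, grid, channels, folder, nZ = 1L,
                      supersample = 1L, experiment = "exp") {
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  srv <- new.env(parent = emptyenv())
  srv$tIndex <- 0L
  srv$position <- c(x_um = 0, y_um = 0, z_um = 0)
  srv$handleLine <- function(line) {
    msg <- tryCatch(decodeMessage(line), error = function(e) e)
    if (inherits(msg, "error"))
      return(encodeMessage(list(err = "parse", detail = "malformed command")))
    cmd <- if ("cmd" %in% names(msg)) msg[["cmd"]] else ""
    if (cmd == "setposition") {
      if ("xpos" %in% names(msg)) srv$position["x_um"] <- as.numeric(msg[["xpos"]])
      if ("ypos" %in% names(msg)) srv$position["y_um"] <- as.numeric(msg[["ypos"]])
      if ("zpos" %in% names(msg)) srv$position["z_um"] <- as.numeric(msg[["zpos"]])
      return(encodeMessage(list(ok = "setposition")))
    }
    if (cmd == "startscan") {
      t <- srv$tIndex
      optics <- opticsState(grid@tileH, grid@tileW, grid@pixelSize,
                            supersample = supersample, nZ = nZ)
      for (r in seq_len(grid@nRows) - 1L) {
        for (cc in seq_len(grid@nCols) - 1L) {
          center <- tileCenter(grid, r, cc)
          for (ci in seq_along(channels)) {
            for (z in seq_len(nZ) - 1L) {
              img <- renderTile(scene, center, channels[ci], zIndex = z,
                                tIndex = t, optics = optics)
              writeImageTiff(img, file.path(folder, formatTileName(
                experiment, t, 0L, r, cc, ci - 1L, z)), scene@spec$bitDepth)
            }
          }
        }
      }
      srv$tIndex <- t + 1L
      return(encodeMessage(list(inf = "scanfinished")))
    }
    if (cmd %in% c("stopscan", "startcycle", "stopcycle"))
      return(encodeMessage(stats::setNames(list(cmd), "ok")))
    # unknown commands pass through for forward compatibility
    encodeMessage(stats::setNames(list(cmd), "ok"))
  }
  srv
}
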