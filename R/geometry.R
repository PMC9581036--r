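#' Convert a tile pixel position to an absolute stage position
#'
#' Pixel coordinates are 0-based and continuous: `px = tileW / 2`,
#' `py = tileH / 2` is the exact tile center; x grows with columns and y grows
#' with rows (downward). Tile (0, 0) is centered on the grid origin and tiles
#' are laid side by side with zero overlap, so tile (row, col) is centered one
#' tile pitch per index away from the origin.
#'
#' @param grid a [TileGrid-class]
#' @param row,col 0-based tile indices
#' @param px,py 0-based continuous pixel coordinates within the tile
#'   (`px` horizontal, `py` vertical)
#' @return named numeric vector `c(x_um, y_um, z_um)`
#' @seealso [stageToPixel()] for the exact inverse
#' @examples
#' g <- TileGrid(c(0, 0, 0), 2, 2, 100, 100, pixelSize = 1)
#' pixelToStage(g, 0, 1, 50, 50)  # one tile pitch to the right
#' @export
pixelToStage <- function(grid, row, col, px, py) {
  if (row < 0 || row >= grid@nRows || col < 0 || col >= grid@nCols)
    stop("index error: tile (", row, ", ", col, ") outside ",
         grid@nRows, " x ", grid@nCols, " grid")
  if (px < 0 || px > grid@tileW || py < 0 || py > grid@tileH)
    stop("index error: pixel (", px, ", ", py, ") outside tile raster")
  p <- grid@pixelSize
  sx <- if (grid@axisFlip[1]) -1 else 1
  sy <- if (grid@axisFlip[2]) -1 else 1
  c(x_um = grid@originX + sx * (col * grid@tileW + px - grid@tileW / 2) * p,
    y_um = grid@originY + sy * (row * grid@tileH + py - grid@tileH / 2) * p,
    z_um = grid@originZ)
}

#' Convert an absolute stage position back to tile/pixel coordinates
#'
#' Exact inverse of [pixelToStage()] for positions inside the grid footprint.
#'
#' @param grid a [TileGrid-class]
#' @param pos numeric length >= 2, stage `(x, y)` in micrometers
#' @return list with `row`, `col` (0-based tile indices) and `px`, `py`
#'   (0-based continuous pixel coordinates)
#' @export
stageToPixel <- function(grid, pos) {
  p <- grid@pixelSize
  sx <- if (grid@axisFlip[1]) -1 else 1
  sy <- if (grid@axisFlip[2]) -1 else 1
  u <- sx * (pos[1] - grid@originX) / p + grid@tileW / 2
  v <- sy * (pos[2] - grid@originY) / p + grid@tileH / 2
  umax <- grid@nCols * grid@tileW
  vmax <- grid@nRows * grid@tileH
  if (u < 0 || u > umax || v < 0 || v > vmax)
    stop("domain error: stage position (", pos[1], ", ", pos[2],
         ") outside the grid footprint")
  col <- min(floor(u / grid@tileW), grid@nCols - 1)
  row <- min(floor(v / grid@tileH), grid@nRows - 1)
  list(row = as.integer(row), col = as.integer(col),
       px = u - col * grid@tileW, py = v - row * grid@tileH)
}

#' Convert assembled-map pixel coordinates to a stage position
#'
#' The assembled map spans the whole grid; `mx`, `my` are 0-based continuous
#' pixel coordinates in the map raster (`mx` horizontal / columns).
#'
#' @param grid a [TileGrid-class]
#' @param mx,my 0-based continuous map pixel coordinates
#' @return named numeric vector `c(x_um, y_um, z_um)`
#' @export
mapPixelToStage <- function(grid, mx, my) {
  p <- grid@pixelSize
  sx <- if (grid@axisFlip[1]) -1 else 1
  sy <- if (grid@axisFlip[2]) -1 else 1
  c(x_um = grid@originX + sx * (mx - grid@tileW / 2) * p,
    y_um = grid@originY + sy * (my - grid@tileH / 2) * p,
    z_um = grid@originZ)
}

#' Stage position of a tile center
#' @param grid a [TileGrid-class]
#' @param row,col 0-based tile indices
#' @return named numeric vector `c(x_um, y_um, z_um)`
#' @export
tileCenter <- function(grid, row, col) {
  pixelToStage(grid, row, col, grid@tileW / 2, grid@tileH / 2)
}

#' Tile visiting order of a grid
#'
#' Row-major order visits tiles left-to-right in every row; serpentine order
#' reverses direction on every other row (the usual stage-travel optimization).
#'
#' @param grid a [TileGrid-class]
#' @return data.frame with 0-based columns `row`, `col`, in visiting order
#' @export
tileOrder <- function(grid) {
  rows <- seq_len(grid@nRows) - 1L
  out <- do.call(rbind, lapply(rows, function(r) {
    cols <- seq_len(grid@nCols) - 1L
    if (grid@scanOrder == "serpentine" && r %% 2L == 1L) cols <- rev(cols)
    data.frame(row = r, col = cols)
  }))
  rownames(out) <- NULL
  out
}

#' Bilinear focus-map interpolation from the four corners of a region
#'
#' Reconstructs a coarse focus surface from z values measured at the corners
#' of the scanned region, as used to keep a long primary scan in focus without
#' per-tile autofocus.
#'
#' @param cornerZ numeric length-4, z in micrometers at (top-left, top-right,
#'   bottom-left, bottom-right)
#' @param u,v normalized coordinates in `[0, 1]`; `u` runs left to right,
#'   `v` top to bottom
#' @return interpolated z in micrometers; exact at the corners
#' @examples
#' focusMapInterpolate(c(0, 10, 20, 30), 0.5, 0.5)  # mean of corners: 15
#' @export
focusMapInterpolate <- function(cornerZ, u, v) {
  stopifnot(length(cornerZ) == 4, all(is.finite(cornerZ)))
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1))
    stop("domain error: u and v must lie in [0, 1]")
  top <- (1 - u) * cornerZ[1] + u * cornerZ[2]
  bot <- (1 - u) * cornerZ[3] + u * cornerZ[4]
  (1 - v) * top + v * bot
}
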