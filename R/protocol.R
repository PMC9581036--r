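#' Text-command messaging dialect for driving the acquisition side
#'
#' The engine talks to the acquisition software (or the built-in simulator)
#' through LF-terminated text lines of space-separated `/key:value` fields, a
#' documented dialect of the text-command style used by commercial microscope
#' remote-control interfaces. Command vocabulary: `/cmd:{startscan, stopscan,
#' setposition, startcycle, stopcycle}`, notification `/inf:scanfinished`,
#' stage fields `/xpos /ypos /zpos` in micrometers as decimal text. Unknown
#' `/cmd` values are passed through for forward compatibility. Values are
#' kept verbatim as text (numbers are not reparsed), so encode/decode is an
#' exact inverse. Dialect version: 1.
#'
#' @param msg named list/character vector of fields; names must be non-empty
#'   and free of whitespace, values must not contain line breaks
#' @return `encodeMessage`: a single LF-terminated line; `decodeMessage`: a
#'   named character vector of fields in wire order
#' @examples
#' encodeMessage(list(cmd = "startscan"))
#' decodeMessage("/cmd:setposition /xpos:1250.5 /ypos:-40\n")
#' @export
encodeMessage <- function(msg) {
  keys <- names(msg)
  vals <- as.character(unlist(msg, use.names = FALSE))
  if (is.null(keys) || any(!nzchar(keys)) || any(grepl("[[:space:]]", keys)))
    stop("protocol error: message keys must be non-empty, without whitespace")
  if (any(grepl("[\r\n]", vals)))
    stop("protocol error: message values must not contain line breaks")
  paste0(paste(sprintf("/%s:%s", keys, vals), collapse = " "), "\n")
}

#' @rdname encodeMessage
#' @param line one LF-terminated message line
#' @export
decodeMessage <- function(line) {
  line <- sub("\n$", "", line)
  if (!nzchar(line)) stop("parse error: empty message line")
  fields <- strsplit(line, " ", fixed = TRUE)[[1]]
  fields <- fields[nzchar(fields)]
  out <- character(length(fields))
  keys <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- sub("^/", "", fields[i])
    ci <- regexpr(":", f, fixed = TRUE)
    if (ci < 1L) stop("parse error: field without ':' in message: ", fields[i])
    keys[i] <- substr(f, 1L, ci - 1L)
    out[i] <- substr(f, ci + 1L, nchar(f))
  }
  names(out) <- keys
  out
}

#' Tile exchange-file naming convention
#'
#' Pattern: `{exp}_t{T:04d}_b{B:03d}_r{R:02d}_c{C:02d}_ch{CH:02d}_z{Z:03d}.tif`
#' — experiment id, primary-scan time index, block, tile row/col, channel and
#' z-slice indices, all 0-based. `formatTileName`/`parseTileName` are lossless
#' inverses; non-conforming names raise a parse error (the folder watcher
#' ignores such files with a warning).
#'
#' @param exp experiment id (no underscores needed; kept verbatim)
#' @param t,b,r,c,ch,z non-negative indices
#' @return `formatTileName`: file name; `parseTileName`: list of fields
#' @examples
#' formatTileName("exp", 0, 0, 0, 0, 0, 0)
#' @export
formatTileName <- function(exp, t, b, r, c, ch, z) {
  stopifnot(all(c(t, b, r, c, ch, z) >= 0))
  sprintf("%s_t%04d_b%03d_r%02d_c%02d_ch%02d_z%03d.tif", exp, t, b, r, c, ch, z)
}

#' @rdname formatTileName
#' @param name a file name (base name, no directory)
#' @export
parseTileName <- function(name) {
  pat <- "^(.+)_t([0-9]{4,})_b([0-9]{3,})_r([0-9]{2,})_c([0-9]{2,})_ch([0-9]{2,})_z([0-9]{3,})\\.tif$"
  m <- regmatches(name, regexec(pat, name))[[1]]
  if (length(m) != 8L)
    stop("parse error: file name does not follow the tile convention: ", name)
  list(exp = m[2], t = as.integer(m[3]), b = as.integer(m[4]),
       r = as.integer(m[5]), c = as.integer(m[6]),
       ch = as.integer(m[7]), z = as.integer(m[8]))
}

# One polling step over the exchange folder: which expected files exist with a
# size unchanged since the previous poll? Returns the new size table and the
# set of stable files. Exposed internally so the stability rule is testable
# without a concurrent writer.
.scanFolderState <- function(folder, expected, prevSizes) {
  paths <- file.path(folder, expected)
  info <- file.info(paths)
  sizes <- info$size
  names(sizes) <- expected
  stable <- !is.na(sizes) & !is.na(prevSizes[expected]) &
            sizes == prevSizes[expected]
  list(sizes = sizes, stable = expected[stable])
}

#' Collect an expected set of tile files from the exchange folder
#'
#' Polls the folder until every expected file exists with a size unchanged
#' across two consecutive polls (a portable stability check for files still
#' being written over a network share), then loads all of them.
#'
#' @param folder exchange folder path
#' @param expected character vector of expected file names
#' @param timeout timeout in seconds
#' @param pollInterval seconds between polls
#' @return named list of image matrices, one per expected name
#' @export
collectScan <- function(folder, expected, timeout = 30, pollInterval = 0.05) {
  deadline <- Sys.time() + timeout
  prev <- stats::setNames(rep(NA_real_, length(expected)), expected)
  repeat {
    st <- .scanFolderState(folder, expected, prev)
    if (length(st$stable) == length(expected))
      return(stats::setNames(
        lapply(file.path(folder, expected), readImageTiff), expected))
    if (Sys.time() > deadline) {
      missing <- setdiff(expected, st$stable)
      stop("timeout error: files missing or unstable after ", timeout,
           " s: ", paste(missing, collapse = ", "))
    }
    prev <- st$sizes
    Sys.sleep(pollInterval)
  }
}

#' Offline replay acquisition backend
#'
#' Serves previously acquired (or simulator-recorded) primary-scan tiles from
#' a folder in `t_index` order, through the same backend contract as the live
#' simulator, so engine code is identical online and offline. Non-conforming
#' file names are ignored with a warning.
#'
#' @param folder folder of tile TIFFs named per [formatTileName()]
#' @param channels character vector naming the channels, in the order of the
#'   `ch` index in the file names
#' @param grid optional [TileGrid-class]; when NULL the grid geometry is
#'   inferred from the tile indices and the first tile's raster (origin 0,
#'   1 micrometer/px)
#' @return a backend list with elements `primary(block, t)`, `secondary(...)`,
#'   `hasFrame(t)`, `nBlocks`, `grids`, `kind = "replay"`
#' @export
replaySource <- function(folder, channels = NULL, grid = NULL) {
  files <- list.files(folder, pattern = "\\.tif$")
  parsed <- list()
  for (f in files) {
    p <- tryCatch(parseTileName(f), error = function(e) NULL)
    if (is.null(p)) { warning("ignoring non-conforming file: ", f); next }
    parsed[[length(parsed) + 1L]] <- c(p, list(file = f))
  }
  if (!length(parsed)) stop("config error: no conforming tile files in ", folder)
  idx <- do.call(rbind, lapply(parsed, function(p)
    data.frame(t = p$t, b = p$b, r = p$r, c = p$c, ch = p$ch, z = p$z,
               file = p$file, stringsAsFactors = FALSE)))
  if (is.null(channels)) channels <- paste0("ch", sort(unique(idx$ch)))
  blocks <- sort(unique(idx$b))
  makeGrid <- function(b) {
    if (!is.null(grid)) return(grid)
    sub <- idx[idx$b == b, ]
    tile1 <- readImageTiff(file.path(folder, sub$file[1]))
    TileGrid(c(0, 0, 0), nRows = max(sub$r) + 1L, nCols = max(sub$c) + 1L,
             tileH = nrow(tile1), tileW = ncol(tile1), pixelSize = 1)
  }
  grids <- lapply(blocks, makeGrid)
  names(grids) <- as.character(blocks)
  tmax <- max(idx$t)
  served_t <- new.env(parent = emptyenv()); served_t$last <- -1L
  list(
    kind = "replay",
    nBlocks = length(blocks),
    grids = grids,
    hasFrame = function(t) t <= tmax,
    primary = function(block, t) {
      if (is.na(block)) block <- blocks[1]   # tiled runs record block 0
      if (t > tmax) stop("exhausted: no stored frame for t = ", t)
      if (t < served_t$last) stop("replay error: t indices must be requested monotonically")
      served_t$last <- t
      g <- grids[[as.character(block)]]
      sub <- idx[idx$b == block & idx$t == t, ]
      if (!nrow(sub)) stop("exhausted: no stored tiles for block ", block, ", t = ", t)
      ncell <- g@nRows * g@nCols
      tiles <- vector("list", ncell)
      for (cell in seq_len(ncell)) {
        r <- (cell - 1L) %/% g@nCols
        cc <- (cell - 1L) %% g@nCols
        perch <- stats::setNames(vector("list", length(channels)), channels)
        for (ci in seq_along(channels)) {
          zf <- sub[sub$r == r & sub$c == cc & sub$ch == ci - 1L, ]
          zf <- zf[order(zf$z), ]
          if (!nrow(zf))
            stop("completeness error: missing tile files for cell (", r, ", ",
                 cc, "), channel ", channels[ci], ", t = ", t)
          perch[[ci]] <- lapply(file.path(folder, zf$file), readImageTiff)
        }
        tiles[[cell]] <- perch
      }
      list(grid = g, tiles = tiles)
    },
    secondary = function(target, k, t, config) invisible(NULL)
  )
}
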