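#' Primitive image operators
#'
#' Images are plain numeric matrices in detector units (`[0, 2^bitDepth - 1]`
#' for integer data). All neighborhood filters use a disk structuring element
#' (`dr^2 + dc^2 <= radius^2`) CLIPPED to the image bounds at the edges — no
#' reflection or padding — which keeps every operator easy to verify against
#' a brute-force per-pixel oracle.
#'
#' @name imgops
NULL

#' Median filter over a disk neighborhood
#'
#' @param img numeric matrix
#' @param radius disk radius in pixels (>= 1)
#' @return filtered matrix, same shape
#' @export
medianFilterDisk <- function(img, radius) {
  if (radius < 1) stop("parameter error: radius must be >= 1")
  cpp_disk_median(img, as.integer(radius))
}

#' Replace outlier pixels by their neighborhood median
#'
#' A pixel `p` with disk-neighborhood median `m` is replaced by `m` iff
#' `p - m > threshold` (mode `"bright"`) or `m - p > threshold` (mode
#' `"dark"`); all other pixels are unchanged. Removes compact high-contrast
#' objects smaller than the disk while leaving extended structures intact —
#' the complement image `img - result` isolates exactly those compact objects.
#'
#' @param img numeric matrix
#' @param radius disk radius in pixels (>= 1)
#' @param threshold non-negative outlier contrast threshold, intensity units
#' @param mode `"bright"` or `"dark"`
#' @return matrix with outliers replaced
#' @export
removeOutliers <- function(img, radius, threshold, mode = c("bright", "dark")) {
  if (radius < 1) stop("parameter error: radius must be >= 1")
  if (threshold < 0) stop("parameter error: threshold must be >= 0")
  mode <- match.arg(mode)
  med <- cpp_disk_median(img, as.integer(radius))
  out <- img
  repl <- if (mode == "bright") (img - med) > threshold else (med - img) > threshold
  out[repl] <- med[repl]
  out
}

#' Clamped image subtraction
#'
#' Per-pixel `max(a - b, 0)`, keeping the unsigned-integer semantics of the
#' source bit depth.
#'
#' @param a,b numeric matrices of equal shape
#' @return matrix `pmax(a - b, 0)`
#' @export
subtractClamped <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape error: images differ in shape (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")")
  pmax(a - b, 0)
}

#' Threshold non-zero pixels
#' @param img numeric matrix
#' @return logical mask, TRUE where `img > 0`
#' @export
thresholdNonzero <- function(img) img > 0

#' Otsu threshold of a 256-bin histogram
#'
#' Exhaustive search over the 255 split points of a 256-bin histogram spanning
#' `[min(img), max(img)]`, maximizing the between-class variance. Returns the
#' intensity value of the chosen bin boundary.
#'
#' @param img numeric matrix
#' @return threshold value on the intensity scale of `img`
#' @export
otsuThreshold <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  bin <- pmin(floor((v - lo) / (hi - lo) * nb), nb - 1L)
  h <- as.numeric(tabulate(bin + 1L, nbins = nb))
  w <- cumsum(h)
  mu <- cumsum(h * (seq_len(nb) - 1L))
  n <- w[nb]; mtot <- mu[nb]
  w1 <- w[-nb]; m1 <- mu[-nb]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (mtot * w1[valid] / n - m1[valid])^2 / (w1[valid] * w2[valid])
  k <- which.max(bcv)                      # first maximum: deterministic
  lo + k / nb * (hi - lo)
}

#' Global image threshold
#'
#' @param img numeric matrix
#' @param method `"otsu"` (256-bin between-class-variance search) or
#'   `"fixed"` (requires `value`)
#' @param value fixed threshold value (intensity units)
#' @return logical mask, TRUE where `img > threshold`
#' @export
thresholdGlobal <- function(img, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(value)) stop("parameter error: method 'fixed' requires a value")
    value
  } else otsuThreshold(img)
  img > thr
}

#' Laplacian-of-Gaussian filter
#'
#' Gaussian smoothing at `sigma` (separable kernel truncated at 3 sigma,
#' replicate edges) followed by the discrete 5-point Laplacian. Sign
#' convention: the response is the raw Laplacian of the smoothed image, so
#' BRIGHT blobs of diameter about `2 * sqrt(2) * sigma` produce local MINIMA
#' of the response and dark blobs produce local maxima. The operator is
#' linear: `logFilter(a * img) = a * logFilter(img)`.
#'
#' @param img numeric matrix
#' @param sigma Gaussian scale in pixels (> 0)
#' @return signed numeric matrix (the filter response)
#' @export
logFilter <- function(img, sigma) {
  stopifnot(sigma > 0)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  g <- cpp_sep_conv(img, k)
  nr <- nrow(g); nc <- ncol(g)
  up    <- g[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- g[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- g[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- g[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + down + left + right - 4 * g
}

#' Significant local minima by topographic prominence
#'
#' A minimum is significant when it lies at least `prominence` below the
#' lowest saddle connecting it to any deeper minimum (topographic prominence,
#' invariant to any constant background offset). Surviving minima are
#' non-maximum-suppressed: candidates are visited in decreasing prominence
#' (ties by row then col) and discarded when within `minDistance` pixels
#' (Euclidean) of an already accepted minimum.
#'
#' @param img numeric matrix
#' @param prominence minimum prominence (>= 0) for a minimum to be reported
#' @param minDistance suppression radius in pixels (>= 1)
#' @return data.frame with 1-based `row`, `col`, `value`, `prominence`,
#'   ordered by decreasing prominence
#' @export
localMinima <- function(img, prominence, minDistance = 1) {
  stopifnot(prominence >= 0, minDistance >= 1)
  cand <- cpp_minima_prominence(img)
  cand <- cand[cand$prominence >= prominence & cand$prominence > 0, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  ord <- order(-cand$prominence, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ki <- which(keep)
    if (!length(ki)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[ki] - cand$row[i])^2 + (cand$col[ki] - cand$col[i])^2
    keep[i] <- all(d2 >= minDistance^2)
  }
  `rownames<-`(cand[keep, , drop = FALSE], NULL)
}

#' Detect blob centers with a Laplacian-of-Gaussian matched filter
#'
#' Convenience wrapper: LoG-filters the image (negating it first for
#' dark-on-bright blobs) and extracts significant response minima.
#'
#' @param img numeric matrix
#' @param sigma blob scale in pixels; for an expected blob diameter `d` use
#'   `d / (2 * sqrt(2))`
#' @param prominence minimum prominence of the response minimum
#' @param minDistance suppression radius in pixels
#' @param dark if TRUE detect dark blobs on a bright background
#' @return data.frame as [localMinima()]
#' @details Two spurious-minimum guards beyond the prominence gate, both
#'   offset-invariant because the Laplacian response is: (1) a reported
#'   minimum must also be DEEP — response value at most `-prominence` —
#'   which rejects the background catchment's own minimum (shallow in value,
#'   yet topologically prominent because every blob is fenced by a positive
#'   response ring); (2) minima closer than `ceiling(2 * sigma)` pixels to
#'   the border are discarded, where the replicate-edge Laplacian is
#'   unreliable and a blob center would be truncated anyway.
#' @export
logBlobs <- function(img, sigma, prominence, minDistance = 3, dark = FALSE) {
  r <- logFilter(if (dark) -img else img, sigma)
  m <- localMinima(r, prominence, minDistance)
  m <- m[m$value <= -prominence, , drop = FALSE]
  b <- ceiling(2 * sigma)
  m <- m[m$row > b & m$row <= nrow(img) - b &
         m$col > b & m$col <= ncol(img) - b, , drop = FALSE]
  `rownames<-`(m, NULL)
}

#' Maximum intensity projection
#' @param stack non-empty list of equally shaped matrices (z slices)
#' @return per-pixel maximum over the slices
#' @export
maxProject <- function(stack) {
  if (!length(stack)) stop("parameter error: empty stack")
  Reduce(pmax, stack)
}

#' Assemble tiles into one contiguous map
#'
#' Tile (r, c) occupies output rows `[r*H, (r+1)*H)` and columns
#' `[c*W, (c+1)*W)` (0-based); tiles are laid side by side with zero overlap,
#' so every input pixel appears exactly once.
#'
#' @param tiles list of matrices in row-major cell order
#'   (`cell = r * nCols + c + 1`), one per grid cell
#' @param grid a [TileGrid-class]
#' @return matrix of size `(nRows*tileH) x (nCols*tileW)`
#' @export
assembleTiles <- function(tiles, grid) {
  H <- grid@tileH; W <- grid@tileW
  out <- matrix(0, nrow = grid@nRows * H, ncol = grid@nCols * W)
  for (r in seq_len(grid@nRows) - 1L) {
    for (cc in seq_len(grid@nCols) - 1L) {
      idx <- r * grid@nCols + cc + 1L
      tile <- if (idx <= length(tiles)) tiles[[idx]] else NULL
      if (is.null(tile))
        stop("completeness error: missing tile for cell (", r, ", ", cc, ")")
      if (!identical(dim(tile), c(H, W)))
        stop("shape error: tile (", r, ", ", cc, ") is not ", H, " x ", W)
      out[r * H + seq_len(H), cc * W + seq_len(W)] <- tile
    }
  }
  out
}

#' Build a review montage of crops around each target
#'
#' Crops a `boxPx`-sided square centered on each target's map position
#' (clipped at the map edge and zero-padded) and tiles the crops row-major in
#' a grid of `nCols` columns. The index map records which montage cell holds
#' which target so a head-less selection file can refer to cells.
#'
#' @param map numeric matrix (assembled primary map, one channel)
#' @param targets a [TargetSet-class]
#' @param grid the [TileGrid-class] of the map
#' @param boxPx crop side in pixels (>= 8)
#' @param nCols montage columns
#' @return list with `montage` (matrix; `0 x 0` for no targets) and
#'   `index` (data.frame: `cell` 0-based montage cell, `target` 1-based row
#'   into the TargetSet)
#' @export
makeMontage <- function(map, targets, grid, boxPx = 32, nCols = 8) {
  stopifnot(boxPx >= 8)
  n <- length(targets)
  if (n == 0L)
    return(list(montage = matrix(0, 0, 0),
                index = data.frame(cell = integer(), target = integer())))
  nrows <- ceiling(n / nCols)
  mont <- matrix(0, nrow = nrows * boxPx, ncol = nCols * boxPx)
  df <- targets@targets
  for (i in seq_len(n)) {
    pp <- stageToPixel(grid, c(df$x_um[i], df$y_um[i]))
    mx <- pp$col * grid@tileW + pp$px   # 0-based continuous map coords
    my <- pp$row * grid@tileH + pp$py
    ci <- floor(mx) + 1L; ri <- floor(my) + 1L
    half <- boxPx %/% 2L
    rows <- (ri - half):(ri - half + boxPx - 1L)
    cols <- (ci - half):(ci - half + boxPx - 1L)
    vr <- rows >= 1L & rows <= nrow(map)
    vc <- cols >= 1L & cols <= ncol(map)
    crop <- matrix(0, boxPx, boxPx)
    crop[which(vr), which(vc)] <- map[rows[vr], cols[vc], drop = FALSE]
    cell <- i - 1L
    mr <- cell %/% nCols; mc <- cell %% nCols
    mont[mr * boxPx + seq_len(boxPx), mc * boxPx + seq_len(boxPx)] <- crop
  }
  list(montage = mont, index = data.frame(cell = seq_len(n) - 1L,
                                          target = seq_len(n)))
}
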