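#' Read / write grayscale TIFF images in detector units
#'
#' Images travel through the exchange folder as single-page grayscale TIFF
#' files, 8- or 16-bit. On disk intensities are the usual unsigned integers;
#' in memory they are numeric matrices on the same `[0, 2^bitDepth - 1]`
#' scale.
#'
#' @param img numeric matrix with values in `[0, 2^bitDepth - 1]`
#' @param path file path
#' @param bitDepth 8 or 16
#' @return `writeImageTiff` returns `path` invisibly; `readImageTiff` returns
#'   a numeric matrix of integer-valued intensities
#' @export
writeImageTiff <- function(img, path, bitDepth = 16L) {
  stopifnot(bitDepth %in% c(8L, 16L))
  scale <- 2^bitDepth - 1
  m <- pmin(pmax(round(img), 0), scale) / scale
  tiff::writeTIFF(m, path, bits.per.sample = as.integer(bitDepth),
                  compression = "none")
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
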