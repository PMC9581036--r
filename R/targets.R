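#' Deduplicate a target list by minimum stage separation
#'
#' Greedy by descending score: a target is kept iff no already-kept target lies
#' within `minSeparation` micrometers (Euclidean distance in the stage XY
#' plane; z is focus, not identity). Ties in score are broken by input order.
#' The survivors are returned in descending-score order, so the result is
#' independent of the input order for distinct scores. This prevents the
#' secondary scan from re-imaging the same object twice.
#'
#' @param targets a [TargetSet-class]
#' @param minSeparation minimum pairwise stage distance, micrometers (>= 0)
#' @return the deduplicated [TargetSet-class]
#' @export
dedupTargets <- function(targets, minSeparation) {
  stopifnot(minSeparation >= 0)
  df <- targets@targets
  if (nrow(df) <= 1L) return(targets)
  ord <- order(-df$score)            # stable: ties keep input order
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ki <- which(keep)
    if (!length(ki)) { keep[i] <- TRUE; next }
    d2 <- (df$x_um[ki] - df$x_um[i])^2 + (df$y_um[ki] - df$y_um[i])^2
    keep[i] <- all(d2 >= minSeparation^2)
  }
  new("TargetSet", targets = `rownames<-`(df[keep, , drop = FALSE], NULL))
}

#' Save / load a target list as CSV
#'
#' Columns: `x_um, y_um, z_um, label, score, frame_index, block_index`.
#' Micrometer fields are written with 6 decimals; the round trip is lossless
#' at that precision. Saved target lists let the same secondary targets be
#' re-acquired in later sessions (e.g. after re-staining the sample).
#'
#' @param targets a [TargetSet-class]
#' @param path file path
#' @return `saveTargets` returns `path` invisibly; `loadTargets` returns a
#'   [TargetSet-class]
#' @export
saveTargets <- function(targets, path) {
  df <- targets@targets
  out <- data.frame(x_um = sprintf("%.6f", df$x_um),
                    y_um = sprintf("%.6f", df$y_um),
                    z_um = sprintf("%.6f", df$z_um),
                    label = df$label,
                    score = sprintf("%.6f", df$score),
                    frame_index = df$frame_index,
                    block_index = df$block_index,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = 4)  # quote label only
  invisible(path)
}

#' @rdname saveTargets
#' @export
loadTargets <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("parse error: empty target file at line 1")
  header <- utils::read.csv(text = lines[1], header = FALSE,
                            stringsAsFactors = FALSE)
  if (!identical(as.character(unlist(header)), .target_cols))
    stop("parse error at line 1: expected header ",
         paste(.target_cols, collapse = ","))
  if (length(lines) == 1L) return(emptyTargets())
  nfield <- vapply(seq_along(lines)[-1], function(i) {
    ncol(utils::read.csv(text = lines[i], header = FALSE))
  }, integer(1))
  bad <- which(nfield != length(.target_cols))
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L, ": expected ",
         length(.target_cols), " fields, found ", nfield[bad[1]])
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(x_um = "numeric", y_um = "numeric",
                                       z_um = "numeric", label = "character",
                                       score = "numeric",
                                       frame_index = "integer",
                                       block_index = "integer"))
  new("TargetSet", targets = df)
}
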