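#' Load and validate an experiment configuration file
#'
#' Reads a JSON or YAML experiment description (decided by file extension),
#' converts FISH signatures given as `{channel, op, count, label}` records
#' under `detector.params.signatures` into [fishSignature()] objects, and
#' validates the whole document through [experimentConfig()]; unknown keys
#' are rejected with the offending key named by its path into the document.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file
#' @return a validated `smartscanConfig`
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("config error: config must be .json, .yaml or .yml: ", path)
  if (!is.null(raw$detector$params$signatures))
    raw$detector$params$signatures <-
      lapply(raw$detector$params$signatures, .parseSignature)
  experimentConfig(raw)
}

# {label, channels: [{channel, op, count}]} -> fishSignature
.parseSignature <- function(s) {
  if (inherits(s, "fishSignature")) return(s)
  if (is.null(s$label) || is.null(s$channels))
    stop("config error at detector.params.signatures: each signature needs ",
         "'label' and 'channels'")
  chIdx <- vapply(s$channels, function(c) as.integer(c$channel), integer(1))
  nch <- max(chIdx)
  counts <- rep(NA_real_, nch)
  ops <- rep("==", nch)
  for (c in s$channels) {
    i <- as.integer(c$channel)
    counts[i] <- as.numeric(c$count)
    ops[i] <- if (is.null(c$op)) "==" else c$op
  }
  fishSignature(s$label, counts, ops)
}

#' Write a run manifest
#'
#' Every engine run through the command-line interface writes exactly one
#' manifest: the configuration echo, package version, seed, start/end status
#' and the paths of all artifacts written.
#'
#' @param path manifest path (JSON)
#' @param config the config used (a list)
#' @param seed the seed used
#' @param status `"completed"` or an error status
#' @param artifacts character vector of artifact paths
#' @return `path`, invisibly
#' @export
writeManifest <- function(path, config, seed, status, artifacts = character()) {
  cfg <- .configForJson(config)
  man <- list(package = "smartscan",
              version = as.character(utils::packageVersion("smartscan")),
              seed = seed, status = status,
              config = cfg, artifacts = artifacts)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, null = "null",
                              force = TRUE, digits = NA), path)
  invisible(path)
}

# JSON-serializable view of a config (TileGrids and signatures -> lists)
.configForJson <- function(x) {
  if (is(x, "TileGrid"))
    return(list(origin = gridOrigin(x), n_rows = x@nRows, n_cols = x@nCols,
                tile_h_px = x@tileH, tile_w_px = x@tileW,
                pixel_size_um = x@pixelSize, order = x@scanOrder))
  if (inherits(x, "fishSignature")) return(unclass(x))
  if (is.list(x)) return(lapply(unclass(x), .configForJson))
  x
}
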