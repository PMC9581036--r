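#' Standard synthetic experiments
#'
#' Four parameterized sample/experiment definitions, one per built-in
#' detection workflow, emulating the sample types the workflows were designed
#' for. Each returns the sample spec, the matching experiment configuration
#' and the detector name, so a complete experiment can be built from a kind
#' string and a seed. These are the package's reference conditions: the
#' object densities, separations, intensity ratios and event schedules are
#' chosen so every planted object is unambiguously detectable, which is what
#' makes them usable as executable ground-truth contracts.
#'
#' * `metaphase` — a 10 x 10 tiled map (100 px tiles, 1 um/px, 3x zoom
#'   ratio to the secondary scan) of 200 asynchronously dividing nuclei, 5 of
#'   which are condensed/mitotic: 3x brighter and 0.4x the radius.
#' * `fish` — a 4 x 4 tiled map (128 px tiles, 0.5 um/px) of 50 sperm
#'   nuclei carrying FISH spots in 3 channels; 10 nuclei have the aberrant
#'   signature (1, 0, 1), the rest (1, 1, 1); 3 z slices.
#' * `micropattern` — one block: a 12 x 12 micropattern grid (40 um pitch)
#'   imaged as a 4 x 4 tiled map (128 px tiles, 1 um/px); per-pattern
#'   occupancy 0/1/2 with probabilities (0.55, 0.15, 0.30) — about 15%
#'   single-cell patterns.
#' * `mitosis_live` — a live 2 x 2 tiled map (128 px tiles, 1 um/px) of 8
#'   tubulin-dark nuclei in bright cytoplasm; 3 nuclear-envelope-breakdown
#'   events scheduled at frames 4, 10 and 16 over 24 frames; secondary
#'   time-lapses of L = 12 frames, N = 3 events.
#'
#' @param kind one of `"metaphase"`, `"fish"`, `"micropattern"`,
#'   `"mitosis_live"`
#' @param seed integer seed
#' @return list with `spec` (a [sampleSpec()]), `config` (a
#'   `smartscanConfig`) and `detector` (name)
#' @export
fixtureSpec <- function(kind = c("metaphase", "fish", "micropattern",
                                 "mitosis_live"), seed = 1L) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  if (kind == "metaphase") {
    grid <- list(origin = c(0, 0, 0), n_rows = 10L, n_cols = 10L,
                 tile_h_px = 100L, tile_w_px = 100L, pixel_size_um = 1)
    spec <- sampleSpec(
      field = c(-50, 950, -50, 950), background = 200, seed = seed,
      nuclei = list(n = 200L, radius_um = 8, intensity = 3000,
                    n_condensed = 5L, condensed_ratio = 3,
                    condensed_radius_factor = 0.4,
                    min_separation_um = 25, edge_margin_um = 15),
      noise = list(read_sigma = 10, poisson = TRUE, gain = 0.1))
    config <- experimentConfig(list(
      mode = "tiled_fixed", experiment = "metaphase", grid = grid,
      channels = "dna", primary = list(supersample = 3L),
      detector = list(name = "metaphase"), seed = seed))
  } else if (kind == "fish") {
    grid <- list(origin = c(0, 0, 0), n_rows = 4L, n_cols = 4L,
                 tile_h_px = 128L, tile_w_px = 128L, pixel_size_um = 0.5)
    spec <- sampleSpec(
      field = c(-32, 224, -32, 224), background = 150, seed = seed,
      nuclei = list(n = 50L, radius_um = 6, intensity = 3000,
                    min_separation_um = 20, edge_margin_um = 10),
      fish = list(n_channels = 3L, normal_counts = c(1, 1, 1),
                  aberrant_counts = c(1, 0, 1), n_aberrant = 10L,
                  spot_intensity = 20000, spot_sigma_um = 0.6,
                  min_spot_separation_um = 4),
      optics = list(psf_sigma_um = 0.5, z_sigma_um = 3),
      noise = list(read_sigma = 10, poisson = TRUE, gain = 0.1))
    config <- experimentConfig(list(
      mode = "tiled_fixed", experiment = "fish", grid = grid,
      channels = c("dna", "fish1", "fish2", "fish3"),
      primary = list(n_z = 3L, z_step_um = 1.5, supersample = 2L),
      detector = list(name = "fish", params = list(signatures = list(
        fishSignature("abnormal_ch2_missing", c(1, 0, 1))))),
      review = list(enabled = FALSE), seed = seed))
  } else if (kind == "micropattern") {
    grid <- list(origin = c(0, 0, 0), n_rows = 4L, n_cols = 4L,
                 tile_h_px = 128L, tile_w_px = 128L, pixel_size_um = 1)
    spec <- sampleSpec(
      field = c(-64, 448, -64, 448), background = 100, seed = seed,
      micropattern = list(n_rows = 12L, n_cols = 12L, pitch_um = 40,
                          origin_um = c(-28, -28), radius_um = 10,
                          intensity = 5000,
                          occupancy_probs = c(0.55, 0.15, 0.30),
                          occupant_radius_um = 3, occupant_intensity = 3000,
                          occupant_jitter_um = 6.5,
                          occupant_min_separation_um = 9),
      optics = list(psf_sigma_um = 0.8, z_sigma_um = 2),
      noise = list(read_sigma = 8, poisson = TRUE, gain = 0.1))
    config <- experimentConfig(list(
      mode = "block_fixed", experiment = "micropattern", blocks = list(grid),
      channels = c("pattern", "dna"), primary = list(supersample = 2L),
      detector = list(name = "micropattern", params = list(
        dapi_channel = "dna",
        pattern_min_area_px = 150, pattern_max_area_px = 500,
        nucleus_diameter_px = 6, nucleus_prominence = 100)),
      seed = seed))
  } else {
    grid <- list(origin = c(0, 0, 0), n_rows = 2L, n_cols = 2L,
                 tile_h_px = 128L, tile_w_px = 128L, pixel_size_um = 1)
    spec <- sampleSpec(
      field = c(-64, 192, -64, 192), background = 200, seed = seed,
      nuclei = list(n = 8L, radius_um = 6, intensity = 3000,
                    min_separation_um = 30, edge_margin_um = 20),
      live = list(n_frames = 24L, brownian_sigma_um = 0.1,
                  tubulin_bg = 3000, nucleus_level = 800, neb_level = 6000,
                  neb_events = data.frame(nucleus = 1:3,
                                          onset = c(4L, 10L, 16L))),
      optics = list(psf_sigma_um = 1, z_sigma_um = 2),
      noise = list(read_sigma = 10, poisson = TRUE, gain = 0.1))
    config <- experimentConfig(list(
      mode = "tiled_live", experiment = "mitosis", grid = grid,
      channels = "tubulin",
      secondary = list(n_timepoints = 12L),
      detector = list(name = "mitosis_live", params = list(
        min_area_px = 60, max_area_px = 500)),
      max_events = 3L, max_primary_frames = 24L, seed = seed))
  }
  list(spec = spec, config = config, detector = config$detector$name)
}

#' Write a ready-to-replay primary-scan fixture folder
#'
#' Builds the named standard scene, records its primary scan tiles (all
#' frames for live kinds) under the exchange naming convention, and writes
#' the ground-truth CSV plus the experiment config alongside. The folder can
#' be replayed with [replaySource()] or the `replay` command.
#'
#' @param kind fixture kind, see [fixtureSpec()]
#' @param outFolder output folder (created)
#' @param seed integer seed
#' @return invisible list with the folder, scene and config
#' @export
writeFixture <- function(kind, outFolder, seed = 1L) {
  fx <- fixtureSpec(kind, seed)
  dir.create(outFolder, showWarnings = FALSE, recursive = TRUE)
  scene <- buildScene(fx$spec)
  backend <- simulatorBackend(scene, fx$config, recordDir = outFolder)
  nFrames <- if (!is.null(fx$spec$live)) scene@nFrames else 1L
  blocks <- if (is.null(fx$config$blocks)) NA_integer_
            else seq_along(fx$config$blocks) - 1L
  for (t in seq_len(nFrames) - 1L)
    for (b in blocks) invisible(backend$primary(b, t))
  saveGroundTruth(scene, file.path(outFolder, "ground_truth.csv"))
  writeManifest(file.path(outFolder, "manifest.json"), fx$config, seed,
                "completed", artifacts = outFolder)
  invisible(list(folder = outFolder, scene = scene, config = fx$config))
}
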