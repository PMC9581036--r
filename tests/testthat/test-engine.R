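test_that("configuration validation applies defaults and names bad keys", {
  minimal <- list(mode = "tiled_fixed",
                  grid = list(n_rows = 2L, n_cols = 2L, tile_h_px = 32L,
                              tile_w_px = 32L, pixel_size_um = 1),
                  channels = "dna", detector = list(name = "metaphase"))
  cfg <- experimentConfig(minimal)
  expect_true(cfg$review$enabled)                  # review on for tiled_fixed
  expect_equal(cfg$target_cap, Inf)                # cap unlimited by default
  expect_error(experimentConfig(c(minimal, list(detecter = list()))),
               "config error at detecter")
  expect_error(experimentConfig(utils::modifyList(minimal,
                                                  list(mode = "tiled_live"))),
               "secondary.n_timepoints")
  expect_error(experimentConfig(list(mode = "sideways")), "config error at mode")
  blockless <- utils::modifyList(minimal, list(mode = "block_fixed"))
  blockless$grid <- NULL
  expect_error(experimentConfig(blockless), "config error at blocks")
})

test_that("a fixed tiled run caps to the top-scoring targets", {
  r <- fixtureRun("metaphase")
  cfg <- r$fx$config
  cfg$target_cap <- 3
  res <- runTiledFixed(cfg, r$backend)
  expect_equal(length(res$targets), 3L)
  full <- detectMetaphase(fixtureMap("metaphase"), r$fx$config$grid)
  top3 <- sort(targetScores(full), decreasing = TRUE)[1:3]
  expect_setequal(targetScores(res$targets), top3)
  # acquired targets are a subset of the detector output
  expect_true(all(as.data.frame(res$targets)$x_um %in% as.data.frame(full)$x_um))
  ev <- logEvents(res$log)
  expect_equal(sum(ev$event == "secondary_frame"), 3L)
  expect_equal(ev$reason[ev$event == "run_end"], "completed")
})

test_that("review selection restricts the secondary scan to accepted cells", {
  r <- fixtureRun("metaphase")
  cfg <- r$fx$config
  sel <- tempfile("sel"); mont <- tempfile(fileext = ".tif")
  writeLines("2", sel)                             # accept montage cell 2 only
  cfg$review$selection_file <- sel
  cfg$review$montage_file <- mont
  res <- runTiledFixed(cfg, r$backend)
  expect_true(file.exists(mont))                   # review montage written
  expect_equal(length(res$targets), 1L)
  full <- detectMetaphase(fixtureMap("metaphase"), cfg$grid)
  expect_equal(as.data.frame(res$targets), as.data.frame(full[3]),
               ignore_attr = TRUE)
  unlink(sel)
})

test_that("apply review accepts all on a missing file and checks ranges", {
  tl <- randomTargets(3)
  idx <- data.frame(cell = 0:2, target = 1:3)
  sel <- tempfile()
  writeLines(c("0", "2"), sel)
  kept <- applyReview(tl, idx, sel)
  expect_equal(as.data.frame(kept), as.data.frame(tl[c(1, 3)]))
  expect_equal(applyReview(tl, idx, tempfile()), tl)     # absent file
  writeLines("5", sel)
  expect_error(applyReview(tl, idx, sel), "selection error")
  unlink(sel)
})

test_that("a run with no detections ends with no secondary scan", {
  registerDetector("never_fires", function(frames, grid, params) emptyTargets(),
                   overwrite = TRUE)
  r <- fixtureRun("metaphase")
  cfg <- r$fx$config
  cfg$detector <- list(name = "never_fires", params = list())
  res <- runTiledFixed(cfg, r$backend)
  ev <- logEvents(res$log)
  expect_equal(length(res$targets), 0L)
  expect_equal(sum(ev$event == "secondary_frame"), 0L)
  expect_equal(ev$reason[ev$event == "run_end"], "no_targets")
})

test_that("block mode accumulates and acquires in one final secondary scan", {
  r <- fixtureRun("micropattern")
  res <- runBlockFixed(r$fx$config, r$backend)
  truth <- groundTruth(r$scene)
  singles <- truth[truth$kind == "pattern" & truth$occupancy == 1, ]
  expect_equal(length(res$targets), nrow(singles))
  expect_true(all(as.data.frame(res$targets)$block_index == 0L))
  ev <- logEvents(res$log)
  expect_false(any(which(ev$event == "secondary_frame") <
                   max(which(ev$event == "detection_call"))))
  expect_equal(sum(ev$event == "mode_switch"), 2L)
})

test_that("a live tiled run acquires every scheduled breakdown, then stops", {
  r <- fixtureRun("mitosis_live")
  res <- runTiledLive(r$fx$config, r$backend)
  ev <- logEvents(res$log)
  truth <- groundTruth(r$scene)
  onsets <- sort(truth$onset_frame[!is.na(truth$onset_frame)])
  bursts <- ev[ev$event == "mode_switch" & ev$to == "to_secondary", ]
  expect_equal(nrow(bursts), length(onsets))
  expect_equal(bursts$t_index, onsets)             # within 1 frame of onset
  expect_equal(sum(ev$event == "secondary_frame"), 3L * 12L)
  expect_true(all(ev$of_l[ev$event == "secondary_frame"] == 12L))
  expect_equal(ev$reason[ev$event == "run_end"], "max_events")
  # frames 0 and 1 are never analyzed; queue refills after each burst
  dcalls <- ev$t_index[ev$event == "detection_call"]
  expect_false(any(dcalls %in% c(0L, 1L)))
  expect_false(any(dcalls %in% c(onsets[1] + 1L, onsets[1] + 2L)))
  # blindness: no detection call between the switch pairs
  sw <- which(ev$event == "mode_switch")
  for (i in seq(1, length(sw), by = 2))
    expect_false(any(ev$event[sw[i]:sw[i + 1]] == "detection_call"))
})

test_that("live runs with N = 1 stop after the first burst", {
  r <- fixtureRun("mitosis_live")
  cfg <- r$fx$config
  cfg$max_events <- 1L
  res <- runTiledLive(cfg, r$backend)
  ev <- logEvents(res$log)
  expect_equal(sum(ev$event == "secondary_frame"), 12L)
  expect_equal(ev$reason[ev$event == "run_end"], "max_events")
  expect_equal(max(ev$t_index, na.rm = TRUE), 4L)  # stopped at the first onset
})

test_that("an event-free live block run scans all blocks to the frame budget", {
  spec <- sampleSpec(field = c(-32, 32, -32, 32), seed = 21,
                     nuclei = list(n = 2L, radius_um = 5,
                                   min_separation_um = 15, edge_margin_um = 15),
                     live = list(n_frames = 6L, brownian_sigma_um = 0.05,
                                 tubulin_bg = 3000, nucleus_level = 800,
                                 neb_level = 6000),
                     noise = list(read_sigma = 8, poisson = TRUE, gain = 0.1))
  scene <- buildScene(spec)
  blk <- list(origin = c(0, 0, 0), n_rows = 1L, n_cols = 1L, tile_h_px = 64L,
              tile_w_px = 64L, pixel_size_um = 1)
  cfg <- experimentConfig(list(
    mode = "block_live", blocks = list(blk, blk, blk), channels = "tubulin",
    secondary = list(n_timepoints = 4L),
    detector = list(name = "mitosis_live"),
    max_events = 2L, max_primary_frames = 5L, seed = 21))
  res <- runBlockLive(cfg, simulatorBackend(scene, cfg))
  ev <- logEvents(res$log)
  expect_equal(sum(ev$event == "primary_frame_start"), 5L * 3L)
  expect_equal(sum(ev$event == "secondary_frame"), 0L)
  expect_equal(ev$reason[ev$event == "run_end"], "max_primary_frames")
  # round-robin: block indices cycle 0,1,2 within every cycle
  pb <- ev$block_index[ev$event == "primary_frame_start"]
  expect_equal(pb, rep(0:2, times = 5))
})

test_that("a live block run bursts immediately within the triggering cycle", {
  spec <- sampleSpec(field = c(-32, 32, -32, 32), seed = 22,
                     nuclei = list(n = 1L, radius_um = 6,
                                   min_separation_um = 5, edge_margin_um = 25),
                     live = list(n_frames = 8L, brownian_sigma_um = 0,
                                 tubulin_bg = 3000, nucleus_level = 800,
                                 neb_level = 6000,
                                 neb_events = data.frame(nucleus = 1L,
                                                         onset = 3L)),
                     noise = list(read_sigma = 8, poisson = TRUE, gain = 0.1))
  scene <- buildScene(spec)
  blk <- list(origin = c(0, 0, 0), n_rows = 1L, n_cols = 1L, tile_h_px = 64L,
              tile_w_px = 64L, pixel_size_um = 1)
  cfg <- experimentConfig(list(
    mode = "block_live", blocks = list(blk, blk), channels = "tubulin",
    secondary = list(n_timepoints = 3L),
    detector = list(name = "mitosis_live"),
    max_events = 1L, max_primary_frames = 8L, seed = 22))
  res <- runBlockLive(cfg, simulatorBackend(scene, cfg))
  ev <- logEvents(res$log)
  # both blocks see the same scene, so block 0 triggers at its t=3 frame,
  # BEFORE block 1's t=3 frame (immediacy within the cycle)
  trig <- which(ev$event == "mode_switch" & ev$to == "to_secondary")
  after <- ev[seq(trig, nrow(ev)), ]
  expect_false(any(after$event == "primary_frame_start" &
                   after$block_index == 1L & after$t_index == 3L))
  expect_equal(ev$block_index[trig - 1L], 0L)
  expect_equal(sum(ev$event == "secondary_frame"), 3L)
})

test_that("the acquisition log survives an ndjson round trip", {
  r <- fixtureRun("mitosis_live")
  res <- runTiledLive(r$fx$config, r$backend)
  p <- tempfile(fileext = ".ndjson")
  writeLog(res$log, p)
  back <- readLog(p)
  expect_equal(logSignature(back), logSignature(res$log))
  unlink(p)
})

test_that("scan-plan arithmetic reproduces the reference acquisition counts", {
  expect_equal(estimateScanPlan(900, 3, 65)$n_images, 175500)
  expect_equal(estimateScanPlan(20736, imagesPerFov = 75)$n_images, 1555200)
  expect_equal(estimateScanPlan(0, 3, 65)$n_images, 0)
  expect_equal(estimateScanPlan(10, 2, 5, bytesPerImage = 1e6)$bytes, 1e8)
  expect_equal(tilesAtSecondaryResolution(10, 10, 3), 900)
  expect_equal(tilesAtSecondaryResolution(7, 5, 1), 35)
  expect_equal(tilesAtSecondaryResolution(2, 3, 2), 24)
})

test_that("offline replay reproduces the live run exactly", {
  d <- fixtureFolder("mitosis_live", 1)
  r <- fixtureRun("mitosis_live", 1)
  live <- runTiledLive(r$fx$config, r$backend)
  replayed <- runTiledLive(r$fx$config,
                           replaySource(d, channels = r$fx$config$channels))
  expect_identical(logSignature(live$log), logSignature(replayed$log))
  expect_identical(as.data.frame(live$targets), as.data.frame(replayed$targets))
})
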