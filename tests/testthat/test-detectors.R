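test_that("the built-in detectors are registered and the registry is guarded", {
  expect_true(all(c("metaphase", "fish", "micropattern", "mitosis_live")
                  %in% listDetectors()))
  expect_error(registerDetector("metaphase", function(...) NULL),
               "registration error")
  nm <- "noop_test_detector"
  registerDetector(nm, function(frames, grid, params) emptyTargets(),
                   overwrite = TRUE)
  expect_true(nm %in% listDetectors())
  expect_equal(length(getDetector(nm)$fun(list(), NULL, list())), 0L)
  expect_error(getDetector("no_such"), "config error")
})

test_that("unknown detector parameters are rejected by name", {
  g <- TileGrid(c(0, 0, 0), 1, 1, 32, 32, 1)
  map <- PrimaryMap(list(dna = matrix(0, 32, 32)), g)
  expect_error(detectMetaphase(map, g, list(median_radiuss = 2)),
               "unknown detector parameter.*median_radiuss")
})

test_that("condensed-chromatin detection has full recall and no false positives", {
  r <- fixtureRun("metaphase")
  map <- fixtureMap("metaphase")
  blank <- PrimaryMap(list(dna = matrix(0, 100, 100)),
                      TileGrid(c(0, 0, 0), 1, 1, 100, 100, 1))
  expect_equal(length(detectMetaphase(blank, blank@grid)), 0L)
  expect_error(detectMetaphase(map, map@grid, list(channel = "gfp")),
               "config error")
  tl <- detectMetaphase(map, map@grid)
  truth <- groundTruth(r$scene)
  cond <- truth[truth$kind == "condensed", ]
  expect_equal(length(tl), nrow(cond))             # recall 1.0, 0 FP
  df <- as.data.frame(tl)
  for (i in seq_len(nrow(df))) {
    d <- sqrt((cond$x_um - df$x_um[i])^2 + (cond$y_um - df$y_um[i])^2)
    expect_lt(min(d), 5)                           # within 5 px (1 um/px)
  }
  # targets stay inside the scanned footprint
  expect_true(all(df$x_um >= -50 & df$x_um <= 950))
  expect_true(all(df$y_um >= -50 & df$y_um <= 950))
  # deterministic given images and params
  expect_identical(as.data.frame(detectMetaphase(map, map@grid)), df)
})

test_that("the minimum-area rule of the condensed-chromatin workflow is exact", {
  # a synthetic map whose only object survives thresholding with 11 px
  g <- TileGrid(c(0, 0, 0), 1, 1, 64, 64, 1)
  img <- matrix(100, 64, 64)
  blob11 <- cbind(rep(30:32, times = 4)[1:11], rep(30:33, each = 3)[1:11])
  img[blob11] <- 5000
  map <- PrimaryMap(list(dna = img), g)
  p <- list(median_radius = 1, outlier_radius = 4, outlier_threshold = 500)
  expect_equal(length(detectMetaphase(map, g, c(p, min_area_px = 12))), 0L)
  img[33, 33] <- 5000                              # 12th pixel
  map12 <- PrimaryMap(list(dna = img), g)
  expect_equal(length(detectMetaphase(map12, g, c(p, min_area_px = 12))), 1L)
})

test_that("FISH phenotype classification matches planted spot counts", {
  r <- fixtureRun("fish")
  map <- fixtureMap("fish")
  sig <- list(fishSignature("abnormal_ch2_missing", c(1, 0, 1)))
  tl <- detectFishPhenotypes(map, map@grid, sig)
  truth <- groundTruth(r$scene)
  ab <- truth[!is.na(truth$spots_ch1) & truth$spots_ch1 == 1 &
              truth$spots_ch2 == 0 & truth$spots_ch3 == 1, ]
  expect_equal(length(tl), nrow(ab))
  expect_true(all(targetLabels(tl) == "abnormal_ch2_missing"))
  df <- as.data.frame(tl)
  for (i in seq_len(nrow(df))) {
    d <- sqrt((ab$x_um - df$x_um[i])^2 + (ab$y_um - df$y_um[i])^2)
    expect_lt(min(d), 2.5)                         # 5 px at 0.5 um/px
  }
  # a signature no nucleus carries matches nothing
  none <- detectFishPhenotypes(map, map@grid,
                               list(fishSignature("impossible", c(2, 2, 2))))
  expect_equal(length(none), 0L)
  # channel count mismatch is a config error
  expect_error(detectFishPhenotypes(map, map@grid,
                                    list(fishSignature("bad", c(1, 0)))),
               "config error")
})

test_that("FISH nuclei of invalid shape or size are excluded", {
  # an oversized unsplittable blob is excluded even with matching spot counts
  g <- TileGrid(c(0, 0, 0), 1, 1, 96, 96, 0.5)
  dapi <- matrix(100, 96, 96)
  for (i in 1:96) for (j in 1:96)
    if ((i - 48)^2 + (j - 48)^2 <= 20^2) dapi[i, j] <- 3000   # area ~1257 px
  fish1 <- paintGaussian(matrix(100, 96, 96), 48, 48, 20000, 1.2)
  fish2 <- matrix(100, 96, 96)
  map <- PrimaryMap(list(dna = dapi, fish1 = fish1, fish2 = fish2), g)
  tl <- detectFishPhenotypes(map, map@grid,
                             list(fishSignature("match", c(1, 0))),
                             list(nucleus_min_area_px = 200,
                                  nucleus_max_area_px = 900))
  expect_equal(length(tl), 0L)
  # the same nucleus within the gates is classified
  tl2 <- detectFishPhenotypes(map, map@grid,
                              list(fishSignature("match", c(1, 0))),
                              list(nucleus_min_area_px = 200,
                                   nucleus_max_area_px = 1500))
  expect_equal(length(tl2), 1L)
})

test_that("signature priority is first match wins, in list order", {
  g <- TileGrid(c(0, 0, 0), 1, 1, 96, 96, 0.5)
  dapi <- matrix(100, 96, 96)
  for (i in 1:96) for (j in 1:96)
    if ((i - 48)^2 + (j - 48)^2 <= 12^2) dapi[i, j] <- 3000
  fish1 <- paintGaussian(matrix(100, 96, 96), 48, 48, 20000, 1.2)
  map <- PrimaryMap(list(dna = dapi, fish1 = fish1), g)
  sigs <- list(fishSignature("at_least_one", c(1), ops = ">="),
               fishSignature("exactly_one", c(1)))
  tl <- detectFishPhenotypes(map, map@grid, sigs,
                             list(nucleus_min_area_px = 100,
                                  nucleus_max_area_px = 900))
  expect_equal(targetLabels(tl), "at_least_one")
})

test_that("micropattern selection keeps exactly-one-nucleus boxes only", {
  r <- fixtureRun("micropattern")
  map <- fixtureMap("micropattern", block = 0L)
  params <- mergedParams("micropattern", r$fx$config)
  tl <- detectIsolatedOnPattern(map, map@grid, r$fx$config$detector$params)
  truth <- groundTruth(r$scene)
  pats <- truth[truth$kind == "pattern", ]
  singles <- pats[pats$occupancy == 1, ]
  expect_equal(length(tl), nrow(singles))
  df <- as.data.frame(tl)
  for (i in seq_len(nrow(df))) {
    d <- sqrt((singles$x_um - df$x_um[i])^2 + (singles$y_um - df$y_um[i])^2)
    expect_lt(min(d), 5)
  }
  # zero- and double-occupancy patterns are never selected
  multi <- pats[pats$occupancy != 1, ]
  for (i in seq_len(nrow(df))) {
    d <- sqrt((multi$x_um - df$x_um[i])^2 + (multi$y_um - df$y_um[i])^2)
    expect_gt(min(d), 10)
  }
})

test_that("micropattern counting is invariant to a constant intensity offset", {
  r <- fixtureRun("micropattern")
  map <- fixtureMap("micropattern", block = 0L)
  shifted <- PrimaryMap(lapply(map@channels, function(m) m + 500),
                        map@grid, map@tIndex, map@blockIndex)
  a <- as.data.frame(detectIsolatedOnPattern(map, map@grid,
                                             r$fx$config$detector$params))
  b <- as.data.frame(detectIsolatedOnPattern(shifted, map@grid,
                                             r$fx$config$detector$params))
  expect_equal(nrow(a), nrow(b))
  expect_equal(a[, c("x_um", "y_um")], b[, c("x_um", "y_um")])
})

test_that("single-cell pattern frequency tracks the occupancy probability", {
  # ~15% singles per 144-pattern block; binomial 99% CI over pooled seeds
  n <- 0; total <- 0
  for (seed in 1:4) {
    r <- fixtureRun("micropattern", seed)
    occ <- r$scene@patterns$occupancy
    n <- n + sum(occ == 1); total <- total + length(occ)
  }
  ci <- stats::qbinom(c(0.005, 0.995), total, 0.15)
  expect_gte(n, ci[1])
  expect_lte(n, ci[2])
})

test_that("mitosis onset requires change, shape, and an underlying nucleus", {
  r <- fixtureRun("mitosis_live")
  cfg <- r$fx$config
  params <- cfg$detector$params
  f2 <- fixtureMap("mitosis_live", t = 2L)
  f3 <- fixtureMap("mitosis_live", t = 3L)
  f4 <- fixtureMap("mitosis_live", t = 4L)   # first breakdown onset
  expect_error(detectMitosisOnset(list(f2, f3), f2@grid, params),
               "parameter error")
  # three identical frames: no change, no candidates
  expect_equal(length(detectMitosisOnset(list(f2, f2, f2), f2@grid, params)), 0L)
  tl <- detectMitosisOnset(list(f2, f3, f4), f4@grid, params)
  expect_equal(length(tl), 1L)
  truth <- groundTruth(r$scene)
  ev <- truth[!is.na(truth$onset_frame) & truth$onset_frame == 4, ]
  df <- as.data.frame(tl)
  expect_lt(sqrt((ev$x_um - df$x_um)^2 + (ev$y_um - df$y_um)^2), 5)
  # an intensity jump with no underlying nucleus minimum is rejected:
  # plant the jump at a spot at least 20 um from every nucleus
  g <- f2@grid
  base <- mapChannel(f2, "tubulin")
  nuc <- truth[grepl("phase|occupant", truth$kind) | truth$kind == "interphase", ]
  cand <- expand.grid(x = seq(-40, 170, 10), y = seq(-40, 170, 10))
  free <- cand[apply(cand, 1, function(p)
    min(sqrt((nuc$x_um - p[1])^2 + (nuc$y_um - p[2])^2)) > 20), ][1, ]
  pp <- stageToPixel(g, c(free$x, free$y))
  jr <- round(pp$row * g@tileH + pp$py); jc <- round(pp$col * g@tileW + pp$px)
  jump <- base
  for (i in 1:nrow(jump)) for (j in 1:ncol(jump))
    if ((i - jr)^2 + (j - jc)^2 <= 6^2) jump[i, j] <- base[i, j] + 3000
  mk <- function(m, t) PrimaryMap(list(tubulin = m), g, t)
  none <- detectMitosisOnset(list(mk(base, 0), mk(base, 1), mk(jump, 2)),
                             g, params)
  expect_equal(length(none), 0L)
})
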