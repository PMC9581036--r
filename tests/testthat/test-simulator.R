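test_that("scene building is seeded, bounded, and validated", {
  empty <- buildScene(sampleSpec(nuclei = list(n = 0L), seed = 3))
  expect_equal(nrow(empty@nuclei), 0L)
  s1 <- buildScene(sampleSpec(nuclei = list(n = 30L), seed = 5))
  s2 <- buildScene(sampleSpec(nuclei = list(n = 30L), seed = 5))
  expect_identical(s1@nuclei, s2@nuclei)
  s3 <- buildScene(sampleSpec(nuclei = list(n = 30L), seed = 6))
  expect_false(identical(s1@nuclei, s3@nuclei))
  # pairwise separation honored
  d <- as.matrix(stats::dist(s1@nuclei[, c("x_um", "y_um")]))
  diag(d) <- Inf
  expect_gte(min(d), 25)
  # impossible packing errors after bounded retries
  expect_error(buildScene(sampleSpec(field = c(0, 40, 0, 40),
                                     nuclei = list(n = 50L,
                                                   min_separation_um = 25,
                                                   edge_margin_um = 0))),
               "generation error")
  expect_error(sampleSpec(nuclei = list(n = 5L, condensed_ratio = 0.5)),
               "condensed_ratio")
  expect_error(sampleSpec(nuclei = list(nn = 5L)), "unknown key")
})

test_that("condensed counts follow the requested fraction across seeds", {
  counts <- vapply(1:10, function(seed) {
    sc <- buildScene(sampleSpec(seed = seed,
                                nuclei = list(n = 200L, min_separation_um = 15,
                                              condensed_fraction = 0.025)))
    sum(sc@nuclei$condensed)
  }, numeric(1))
  total <- sum(counts)                       # pooled Binomial(2000, 0.025)
  ci <- stats::qbinom(c(0.005, 0.995), 2000, 0.025)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("rendering is deterministic and centers objects correctly", {
  spec <- sampleSpec(field = c(-32, 32, -32, 32), seed = 2,
                     nuclei = list(n = 1L, radius_um = 6, edge_margin_um = 25,
                                   min_separation_um = 1),
                     noise = list(read_sigma = 0, poisson = FALSE))
  scene <- buildScene(spec)
  opt <- opticsState(64, 64, 1)
  ctr <- c(scene@nuclei$x_um[1], scene@nuclei$y_um[1])
  img <- renderTile(scene, ctr, "dna", optics = opt)
  amax <- which(img == max(img), arr.ind = TRUE)
  expect_lte(min(abs(amax[, "row"] - 32.5)), 1)
  expect_lte(min(abs(amax[, "col"] - 32.5)), 1)
  spec2 <- sampleSpec(field = c(-32, 32, -32, 32), seed = 2,
                      nuclei = list(n = 1L, radius_um = 6, edge_margin_um = 25,
                                    min_separation_um = 1),
                      noise = list(read_sigma = 12, poisson = TRUE))
  sc2 <- buildScene(spec2)
  expect_identical(renderTile(sc2, ctr, "dna", optics = opt),
                   renderTile(sc2, ctr, "dna", optics = opt))
  # far outside the field: background + noise only
  far <- renderTile(sc2, c(5000, 5000), "dna", optics = opt)
  expect_lt(mean(far), 250)        # background plus zero-mean noise
  expect_lt(max(far), 200 + 6 * sqrt(200 / 0.1 + 12^2))
})

test_that("an isolated Gaussian object conserves its analytic mass", {
  spec <- sampleSpec(field = c(-32, 32, -32, 32), seed = 4,
                     nuclei = list(n = 1L, radius_um = 0.001,
                                   intensity = 0, edge_margin_um = 31,
                                   min_separation_um = 0),
                     fish = list(n_channels = 1L, normal_counts = 1,
                                 spot_intensity = 5000, spot_sigma_um = 2),
                     background = 0,
                     noise = list(read_sigma = 0, poisson = FALSE))
  scene <- buildScene(spec)
  sp <- scene@spots
  img <- renderTile(scene, c(sp$x_um[1], sp$y_um[1]), "fish1",
                    optics = opticsState(64, 64, 1))
  expect_lt(abs(sum(img) / (5000 * 2 * pi * 2^2) - 1), 0.02)
})

test_that("a coarse primary render equals the block mean of the fine render", {
  spec <- sampleSpec(field = c(-32, 32, -32, 32), seed = 6,
                     nuclei = list(n = 3L, radius_um = 5, edge_margin_um = 10,
                                   min_separation_um = 15),
                     noise = list(read_sigma = 0, poisson = FALSE))
  scene <- buildScene(spec)
  coarse <- renderTile(scene, c(0, 0), "dna",
                       optics = opticsState(32, 32, 2, supersample = 2))
  fine <- renderTile(scene, c(0, 0), "dna",
                     optics = opticsState(64, 64, 1, supersample = 1))
  bm <- smartscan:::.blockMean(fine, 2)
  expect_lt(max(abs(coarse - bm)), 1 + 1e-9)       # integer rounding only
})

test_that("nuclear envelope breakdown raises the tubulin disk to its level", {
  spec <- sampleSpec(field = c(-40, 40, -40, 40), seed = 8,
                     nuclei = list(n = 1L, radius_um = 6, edge_margin_um = 30,
                                   min_separation_um = 1),
                     live = list(n_frames = 6L, brownian_sigma_um = 0,
                                 tubulin_bg = 3000, nucleus_level = 800,
                                 neb_level = 6000,
                                 neb_events = data.frame(nucleus = 1L,
                                                         onset = 3L)),
                     noise = list(read_sigma = 0, poisson = FALSE))
  scene <- buildScene(spec)
  ctr <- c(scene@nuclei$x_um[1], scene@nuclei$y_um[1])
  opt <- opticsState(64, 64, 1)
  pre <- renderTile(scene, ctr, "tubulin", tIndex = 2L, optics = opt)
  post <- renderTile(scene, ctr, "tubulin", tIndex = 3L, optics = opt)
  disk <- matrix(FALSE, 64, 64)
  for (i in 1:64) for (j in 1:64)
    if ((i - 32.5)^2 + (j - 32.5)^2 <= 4^2) disk[i, j] <- TRUE
  expect_lt(abs(mean(pre[disk]) / 800 - 1), 0.1)
  expect_lt(abs(mean(post[disk]) / 6000 - 1), 0.1)
  expect_lt(abs((mean(post[disk]) - mean(pre[disk])) / 5200 - 1), 0.1)
})

test_that("the acquisition server writes the scan and stays alive on errors", {
  spec <- sampleSpec(field = c(-32, 32, -32, 32), seed = 1,
                     nuclei = list(n = 2L, min_separation_um = 10,
                                   edge_margin_um = 10))
  scene <- buildScene(spec)
  folder <- tempfile("exchange")
  srv <- camServer(scene, TileGrid(c(0, 0, 0), 2, 2, 16, 16, 2), "dna",
                   folder, nZ = 3)
  expect_equal(srv$handleLine(encodeMessage(list(cmd = "stopscan"))),
               "/ok:stopscan\n")
  expect_equal(length(list.files(folder, pattern = "\\.tif$")), 0L)
  reply <- srv$handleLine(encodeMessage(list(cmd = "startscan")))
  expect_equal(reply, "/inf:scanfinished\n")
  files <- list.files(folder, pattern = "\\.tif$")
  expect_equal(length(files), 2 * 2 * 1 * 3)       # tiles x channels x z
  # a second scan gets a distinct t index in the file names
  srv$handleLine(encodeMessage(list(cmd = "startscan")))
  t_idx <- vapply(list.files(folder, pattern = "\\.tif$"),
                  function(f) parseTileName(f)$t, integer(1))
  expect_setequal(unique(t_idx), c(0L, 1L))
  # malformed command: error reply, server still answers
  expect_match(srv$handleLine("garbage line\n"), "^/err:parse")
  expect_equal(srv$handleLine(encodeMessage(list(cmd = "stopcycle"))),
               "/ok:stopcycle\n")
  # setposition updates the stored stage position
  srv$handleLine("/cmd:setposition /xpos:1250.5 /ypos:-40\n")
  expect_equal(unname(srv$position[c("x_um", "y_um")]), c(1250.5, -40))
})

test_that("fixture folders are byte-identical under the same seed", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  writeFixture("mitosis_live", d1, seed = 11)
  writeFixture("mitosis_live", d2, seed = 11)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in setdiff(f1, "manifest.json"))          # manifest echoes paths
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  unlink(c(d1, d2), recursive = TRUE)
})
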