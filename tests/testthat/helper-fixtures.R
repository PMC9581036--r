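# Shared fixtures and brute-force oracles. Scene/map construction is cached
# per (kind, seed) because rendering a full tiled map is the slow part.

.fx_cache <- new.env(parent = emptyenv())

fixtureRun <- function(kind, seed = 1L) {
  key <- paste(kind, seed)
  if (is.null(.fx_cache[[key]])) {
    fx <- fixtureSpec(kind, seed)
    scene <- buildScene(fx$spec)
    .fx_cache[[key]] <- list(fx = fx, scene = scene,
                             backend = simulatorBackend(scene, fx$config))
  }
  .fx_cache[[key]]
}

# assembled, max-projected primary map of a fixture (cached)
fixtureMap <- function(kind, seed = 1L, block = NA_integer_, t = 0L) {
  key <- paste("map", kind, seed, block, t)
  if (is.null(.fx_cache[[key]])) {
    r <- fixtureRun(kind, seed)
    .fx_cache[[key]] <- smartscan:::.acquireFrame(
      r$backend, block, t, r$fx$config, smartscan:::.newLog())
  }
  .fx_cache[[key]]
}

# recorded fixture folder, cached for the test session
fixtureFolder <- function(kind, seed = 1L) {
  key <- paste("folder", kind, seed)
  if (is.null(.fx_cache[[key]])) {
    d <- file.path(tempdir(), paste0("fxdir_", kind, "_", seed))
    if (!dir.exists(d)) writeFixture(kind, d, seed)
    .fx_cache[[key]] <- d
  }
  .fx_cache[[key]]
}

mergedParams <- function(kind, config) {
  smartscan:::.mergeParams(config$detector$params,
                           get(paste0(".", kind, "_defaults"),
                               envir = asNamespace("smartscan")))
}

# ---- brute-force oracles ---------------------------------------------------

oracleDiskMedian <- function(img, r) {
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > r^2) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img))
        vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- stats::median(vals)
  }
  out
}

oracleRemoveOutliers <- function(img, r, thr, mode) {
  med <- oracleDiskMedian(img, r)
  out <- img
  repl <- if (mode == "bright") (img - med) > thr else (med - img) > thr
  out[repl] <- med[repl]
  out
}

# exhaustive between-class-variance search over the same 256-bin histogram
oracleOtsu <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  bin <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  best <- -Inf; bestK <- 1
  for (k in 1:255) {
    g1 <- bin < k; g2 <- !g1
    if (!any(g1) || !any(g2)) next
    bcv <- sum(g1) * sum(g2) * (mean(bin[g1]) - mean(bin[g2]))^2
    if (bcv > best) { best <- bcv; bestK <- k }
  }
  lo + bestK / 256 * (hi - lo)
}

# independent 8-connected labeling by breadth-first search (pure R)
oracleParticleAreas <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  areas <- integer(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE; a <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; a <- a + 1L
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
    areas <- c(areas, a)
  }
  sort(areas)
}

randImg <- function(nr, nc, maxv = 255) {
  matrix(sample.int(maxv + 1L, nr * nc, replace = TRUE) - 1L, nr, nc)
}

# render a soft disk / gaussian into a matrix (independent of the simulator)
paintGaussian <- function(img, cy, cx, amp, sigma) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    img[i, j] <- img[i, j] + amp * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2))
  img
}

randomTargets <- function(n, seed = 1) {
  set.seed(seed)
  targetSet(x_um = round(stats::runif(n, -500, 500), 4),
            y_um = round(stats::runif(n, -500, 500), 4),
            z_um = round(stats::runif(n, -10, 10), 4),
            label = sample(c("a", "b"), n, TRUE),
            score = round(stats::runif(n, 0, 10), 4),
            frame_index = sample.int(5L, n, TRUE) - 1L,
            block_index = sample(c(NA_integer_, 0L, 1L), n, TRUE))
}
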