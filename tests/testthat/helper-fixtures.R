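## Shared fixtures, all generated in code.

## tiny benchmark spec for fast ML tests
tinyBenchmark <- function(n = 30, seed = 1L, knob = 0.6) {
  defaultBenchmark(nTracesPerGroup = n, seed = seed, effectKnob = knob)
}

## fast experiment config (small canvas, small forest)
tinyExperimentConfig <- function(...) {
  experimentConfig(renderConfig = RenderConfig(canvasPx = c(64, 96)),
                   gridPx = c(8, 16), rowBandsPerTile = 16,
                   widthLevelsPerTile = 6, numTrees = 100, ...)
}

## constant-gray toy images with group labels, as WaveformImage objects
toyImage <- function(level, group, id, dim = c(32, 32)) {
  new("WaveformImage", pixels = matrix(level, dim[1], dim[2]),
      roiId = id, group = group, metadata = list(), configHash = "toy")
}

## linearly separable toy set: dark = negative, bright = positive, with a
## little deterministic texture so features are not all identical
toyImageSet <- function(nPerClass = 30, seed = 1) {
  set.seed(seed)
  imgs <- list()
  for (i in seq_len(nPerClass)) {
    m <- matrix(0.05 + 0.02 * sin(seq_len(32) / 3 + i), 32, 32)
    imgs[[length(imgs) + 1L]] <-
      new("WaveformImage", pixels = m, roiId = sprintf("neg_%03d", i),
          group = "negative", metadata = list(), configHash = "toy")
  }
  for (i in seq_len(nPerClass)) {
    m <- matrix(0.9 + 0.02 * cos(seq_len(32) / 3 + i), 32, 32)
    imgs[[length(imgs) + 1L]] <-
      new("WaveformImage", pixels = m, roiId = sprintf("pos_%03d", i),
          group = "positive", metadata = list(), configHash = "toy")
  }
  imgs
}

## flat dF/F trace of n samples
flatDff <- function(n = 300, value = 0, dt = 1) {
  CalciumTrace(rep(value, n), frameIntervalS = dt, units = "dff",
               roiId = "flat")
}

## dF/F trace with Gaussian noise and optional injected template spikes
noisyTrace <- function(n = 300, sigma = 0.05, spikeTimes = integer(0),
                       spikeAmp = 0, seed = 1, dt = 1) {
  set.seed(seed)
  v <- rnorm(n, 0, sigma)
  for (t0 in spikeTimes) {
    idx <- t0:min(n, t0 + 10)
    v[idx] <- v[idx] + spikeAmp * exp(-(idx - t0) / 2.5)
  }
  CalciumTrace(v, frameIntervalS = dt, units = "dff", roiId = "inj")
}

## independent point-in-hexagon oracle: explicit convex-polygon test against
## the hexagon vertex ring (flat-top, circumradius R)
hexOracleMembership <- function(rois) {
  labels <- roiLabels(rois)
  H <- nrow(labels); W <- ncol(labels)
  R <- rois@diameterUm / rois@pixelSizeUm / 2
  centers <- roiCenters(rois)
  out <- matrix(0L, H, W)
  ang <- seq(0, 5) * pi / 3
  for (k in seq_len(nrow(centers))) {
    vx <- centers[k, "col"] + R * cos(ang)
    vy <- centers[k, "row"] + R * sin(ang)
    rr <- max(0, floor(centers[k, "row"] - R)):min(H - 1, ceiling(centers[k, "row"] + R))
    cc <- max(0, floor(centers[k, "col"] - R)):min(W - 1, ceiling(centers[k, "col"] + R))
    for (py in rr) for (px in cc) {
      inside <- TRUE
      for (e in 1:6) {
        j <- e %% 6 + 1
        cross <- (vx[j] - vx[e]) * (py - vy[e]) - (vy[j] - vy[e]) * (px - vx[e])
        if (cross < 0) { inside <- FALSE; break }
      }
      if (inside) out[py + 1, px + 1] <- k
    }
  }
  out
}
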