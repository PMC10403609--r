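test_that("preprocessing is the identity at the identity configuration", {
  mv <- simulateMovie(MovieSpec(heightPx = 32, widthPx = 32, nCells = 1,
                      params = TraceParams(durationS = 10)), seed = 1)
  pp <- preprocessMovie(mv, contrastPercentiles = c(0, 100),
                        smoothSigmaPx = 0)
  expect_equal(movieFrames(pp), movieFrames(mv))

  # constant movie stays constant
  cm <- FluorescenceMovie(array(7, dim = c(16, 16, 5)))
  expect_true(all(movieFrames(preprocessMovie(cm, c(1, 99), 1)) == 7))

  # smoothing i.i.d. noise strictly reduces per-pixel temporal variance
  set.seed(1)
  nz <- FluorescenceMovie(array(rnorm(24 * 24 * 40), dim = c(24, 24, 40)))
  sm <- preprocessMovie(nz, c(0, 100), smoothSigmaPx = 1)
  vIn <- mean(apply(movieFrames(nz), c(1, 2), var))
  vOut <- mean(apply(movieFrames(sm), c(1, 2), var))
  expect_lt(vOut, vIn)

  expect_error(preprocessMovie(mv, c(50, 10)), "Percentiles")
})

test_that("hexagonal tiling matches the brute-force point-in-hexagon oracle", {
  for (shape in list(c(64, 64), c(96, 128))) {
    rois <- hexTiling(shape, pixelSizeUm = 1, diameterUm = 20)
    oracle <- hexOracleMembership(rois)
    expect_identical(roiLabels(rois), oracle)
  }
  # finer pixels too
  rois2 <- hexTiling(c(80, 80), pixelSizeUm = 2, diameterUm = 20)
  expect_identical(roiLabels(rois2), hexOracleMembership(rois2))
})

test_that("hexagonal tiling partitions pixels and respects units", {
  rois <- hexTiling(c(128, 128), pixelSizeUm = 1, diameterUm = 20)
  lab <- roiLabels(rois)
  # every assigned pixel belongs to exactly one ROI, and all ROIs are used
  counts <- tabulate(lab[lab > 0], nRois(rois))
  expect_true(all(counts > 0))
  expect_identical(sum(counts), sum(lab > 0))
  # hexagon area ~ (3 sqrt(3) / 8) d^2 ~ 260 px^2 at 20 px across corners
  expect_true(all(abs(counts - 260) < 30))

  # unit conversion: 0.5 um/px doubles the pixel diameter
  r1 <- hexTiling(c(200, 200), pixelSizeUm = 0.5, diameterUm = 20)
  lab1 <- roiLabels(r1)
  px1 <- tabulate(lab1[lab1 > 0], nRois(r1))
  expect_true(all(abs(px1 - 4 * 260) < 80))

  # degenerate frame: no complete hexagon fits
  expect_identical(nRois(hexTiling(c(10, 10), 1, 20)), 0L)
  # too-coarse resolution
  expect_error(hexTiling(c(64, 64), pixelSizeUm = 10, diameterUm = 20),
               "resolution error")
})

test_that("trace extraction averages ROI pixels frame by frame", {
  cm <- FluorescenceMovie(array(3.5, dim = c(64, 64, 12)))
  rois <- hexTiling(c(64, 64), 1, 20)
  trs <- extractTraces(cm, rois)
  expect_length(trs, nRois(rois))
  for (tr in trs[1:2]) {
    expect_identical(length(traceValues(tr)), 12L)
    expect_true(all(traceValues(tr) == 3.5))
  }

  # a flashing cell modulates only the ROIs that overlap it
  spec <- MovieSpec(heightPx = 64, widthPx = 64, nCells = 1,
                    params = TraceParams(durationS = 60, sparkRateHz = 0.1),
                    backgroundNoiseSd = 0)
  mv <- simulateMovie(spec, seed = 4)
  trs <- extractTraces(mv, rois)
  sds <- vapply(trs, function(t) sd(traceValues(t)), numeric(1))
  ctr <- mv@metadata$truth$centers
  d <- sqrt((roiCenters(rois)[, "row"] - ctr[1, "row"])^2 +
            (roiCenters(rois)[, "col"] - ctr[1, "col"])^2)
  expect_true(all(sds[d > 25] < 1e-9))
  expect_gt(max(sds[d < 15]), 0)
})

test_that("noise estimation recovers sigma and the baseline", {
  # pure Gaussian noise: sigma within 15% (median over seeds)
  ratios <- vapply(1:60, function(s) {
    tr <- simulateTrace(TraceParams(sparkRateHz = 0, waveRateHz = 0,
                                    noiseSigma = 0.05), seed = s)
    estimateNoise(tr)@sigma / 5
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1), 0.15)

  # constant trace
  ne <- estimateNoise(CalciumTrace(rep(4, 100), units = "raw"))
  expect_identical(ne@sigma, 0)
  expect_identical(ne@f0, 4)

  # sparse large spikes do not corrupt the estimate (within 20%)
  ratios2 <- vapply(1:40, function(s) {
    tr <- noisyTrace(300, sigma = 0.05,
                     spikeTimes = c(30, 90, 150, 210, 270), spikeAmp = 0.5,
                     seed = s)
    estimateNoise(tr)@sigma / 0.05
  }, numeric(1))
  expect_lt(abs(median(ratios2) - 1), 0.20)

  expect_error(estimateNoise(CalciumTrace(rnorm(10), units = "dff")),
               "input error")
})

test_that("spike detection finds injected events and rejects noise", {
  # flat trace: no spikes
  flat <- flatDff(300)
  expect_identical(nSpikes(detectSpikes(flat,
    new("NoiseEstimate", f0 = 0, sigma = 0.05, units = "dff"))), 0L)

  # five 10-sigma events >= 10 samples apart are recovered exactly, +-1 sample
  inj <- c(30, 80, 130, 200, 260)
  tr <- noisyTrace(300, sigma = 0.05, spikeTimes = inj, spikeAmp = 0.5,
                   seed = 3)
  sp <- detectSpikes(tr, new("NoiseEstimate", f0 = 0, sigma = 0.05,
                             units = "dff"), kSigma = 4)
  expect_identical(nSpikes(sp), 5L)
  expect_true(all(abs(spikeTimes(sp) - (inj - 1)) <= 1))
  expect_true(all(spikeAmplitudes(sp) >= sp@threshold))

  # 1-sigma excursions stay below a 4-sigma threshold
  tr1 <- noisyTrace(300, sigma = 0.05, seed = 9)
  sp1 <- detectSpikes(tr1, new("NoiseEstimate", f0 = 0, sigma = 0.05,
                               units = "dff"), kSigma = 4)
  expect_identical(nSpikes(sp1), 0L)

  # zero sigma with a non-constant trace is guarded
  expect_error(detectSpikes(noisyTrace(100, sigma = 0.02, seed = 2),
    new("NoiseEstimate", f0 = 0, sigma = 0, units = "dff")),
    "numeric guard")
})

test_that("spiking-ROI selection filters by spike count and checks alignment", {
  traces <- list(flatDff(100), noisyTrace(100, 0.05, c(20, 60), 0.5, seed = 1),
                 flatDff(100))
  traces[[1]]@roiId <- "a"; traces[[2]]@roiId <- "b"; traces[[3]]@roiId <- "c"
  dets <- lapply(traces, function(tr)
    detectSpikes(tr, new("NoiseEstimate", f0 = 0, sigma = 0.05,
                         units = "dff")))
  sel <- selectSpikingRois(traces, dets, minSpikes = 1)
  expect_identical(vapply(sel$traces, roiId, character(1)), "b")

  # min_spikes = 0 keeps everything, order preserved
  sel0 <- selectSpikingRois(traces, dets, minSpikes = 0)
  expect_identical(vapply(sel0$traces, roiId, character(1)), c("a", "b", "c"))

  expect_error(selectSpikingRois(traces, rev(dets)), "alignment error")
})

test_that("movie-to-spikes recovery is exact for an isolated cell", {
  # one cell, a few large well-separated sparks; full pipeline recovers them
  p <- TraceParams(durationS = 120, sparkRateHz = 0, noiseSigma = 0.01,
                   waveRateHz = 0)
  spec <- MovieSpec(heightPx = 64, widthPx = 64, nCells = 1, params = p,
                    backgroundLevel = 10, backgroundNoiseSd = 0.5)
  mv <- simulateMovie(spec, seed = 6)
  # inject 5 sparks manually into the cell footprint via a fresh trace
  truthTimes <- c(15, 40, 65, 90, 110)
  v <- traceValues(mv@metadata$truth$traces[[1]])
  arr <- movieFrames(mv)
  ctr <- mv@metadata$truth$centers
  rows <- matrix(rep(seq_len(64) - 1, 64), 64, 64)
  cols <- matrix(rep(seq_len(64) - 1, each = 64), 64, 64)
  mask <- which((rows - ctr[1, 1])^2 + (cols - ctr[1, 2])^2 <= 7^2)
  for (t0 in truthTimes) {
    idx <- t0:min(120, t0 + 12)
    bump <- 100 * exp(-(idx - t0) / 3)
    for (j in seq_along(idx))
      arr[mask + (idx[j] - 1) * 64 * 64] <- arr[mask + (idx[j] - 1) * 64 * 64] + bump[j]
  }
  mv2 <- FluorescenceMovie(arr, frameIntervalS = 1)
  pp <- preprocessMovie(mv2, c(0, 100), smoothSigmaPx = 1)
  rois <- hexTiling(c(64, 64), 1, 20)
  trs <- extractTraces(pp, rois)
  dets <- lapply(trs, detectSpikes)
  counts <- vapply(dets, nSpikes, integer(1))
  d <- sqrt((roiCenters(rois)[, "row"] - ctr[1, 1])^2 +
            (roiCenters(rois)[, "col"] - ctr[1, 2])^2)
  expect_identical(max(counts[d < 12]), 5L)
  expect_true(all(counts[d > 30] == 0L))
})

test_that("detected spike counts recover the configured event rate", {
  # 0.05 Hz over 300 s: mean detected count within 2 standard errors of 15
  counts <- vapply(1:100, function(s) {
    tr <- simulateTrace(TraceParams(sparkRateHz = 0.05), seed = 9000 + s)
    nSpikes(detectSpikes(tr, estimateNoise(tr)))
  }, integer(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 15), 2 * se)
})
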