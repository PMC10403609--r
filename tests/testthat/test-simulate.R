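test_that("simulated traces have the recording geometry and are deterministic", {
  tr <- simulateTrace(TraceParams(), seed = 7)
  expect_s4_class(tr, "CalciumTrace")
  expect_identical(length(traceValues(tr)), 300L)
  expect_identical(traceUnits(tr), "raw")

  # non-integer duration/interval ratio rounds up
  tr2 <- simulateTrace(TraceParams(durationS = 10, frameIntervalS = 0.7),
                       seed = 1)
  expect_identical(length(traceValues(tr2)), as.integer(ceiling(10 / 0.7)))

  # bitwise determinism
  a <- simulateTrace(TraceParams(), seed = 42)
  b <- simulateTrace(TraceParams(), seed = 42)
  expect_identical(traceValues(a), traceValues(b))
  c <- simulateTrace(TraceParams(), seed = 43)
  expect_false(identical(traceValues(a), traceValues(c)))
})

test_that("the no-event, no-noise trace is the constant baseline", {
  p <- TraceParams(sparkRateHz = 0, waveRateHz = 0, noiseSigma = 0,
                   baselineF0 = 123)
  tr <- simulateTrace(p, seed = 5)
  expect_equal(traceValues(tr), rep(123, 300))
})

test_that("invalid trace parameters fail naming the offending field", {
  expect_error(TraceParams(durationS = -1), "durationS")
  expect_error(TraceParams(frameIntervalS = 0), "frameIntervalS")
  expect_error(TraceParams(sparkRateHz = -0.1), "sparkRateHz")
  expect_error(TraceParams(noiseSigma = -1), "noiseSigma")
  expect_error(TraceParams(effectKnob = 1.5), "effectKnob")
})

test_that("the effect knob changes kinetics but not rate or amplitude draws", {
  m <- effectMultipliers(1)
  expect_gt(m["decay"], 1)
  expect_gt(m["rise"], 1)
  # identical seeds, different knob: same event times and amplitudes
  t0 <- simulateTrace(TraceParams(effectKnob = 0, noiseSigma = 0), seed = 11)
  t1 <- simulateTrace(TraceParams(effectKnob = 1, noiseSigma = 0), seed = 11)
  expect_identical(traceMetadata(t0)$truth$sparkTimes,
                   traceMetadata(t1)$truth$sparkTimes)
  expect_identical(traceMetadata(t0)$truth$sparkAmps,
                   traceMetadata(t1)$truth$sparkAmps)
  expect_gt(traceMetadata(t1)$truth$tauDecay,
            traceMetadata(t0)$truth$tauDecay)
})

test_that("benchmarks label two groups and enforce matched parameters", {
  spec <- BenchmarkSpec(nTracesPerGroup = 5, seed = 3)
  tr <- makeBenchmark(spec)
  expect_length(tr, 10L)
  groups <- vapply(tr, function(x) traceMetadata(x)$group, character(1))
  expect_identical(as.vector(table(groups)[c("negative", "positive")]),
                   c(5L, 5L))
  # only effectKnob may differ between the group parameter sets
  expect_error(
    BenchmarkSpec(negativeParams = TraceParams(sparkRateHz = 0.02),
                  positiveParams = TraceParams(sparkRateHz = 0.10)),
    "effectKnob")
  # reproducible from the benchmark seed
  tr2 <- makeBenchmark(spec)
  expect_identical(traceValues(tr[[3]]), traceValues(tr2[[3]]))
})

test_that("simulated movies have the declared shape and ground truth", {
  spec <- MovieSpec(heightPx = 64, widthPx = 64, nCells = 2,
                    params = TraceParams(durationS = 30))
  mv <- simulateMovie(spec, seed = 2)
  expect_identical(dim(movieFrames(mv)), c(64L, 64L, 30L))
  expect_identical(nFrames(mv), 30L)
  truth <- mv@metadata$truth
  expect_length(truth$traces, 2L)
  expect_identical(nrow(truth$centers), 2L)

  # determinism
  mv2 <- simulateMovie(spec, seed = 2)
  expect_identical(movieFrames(mv), movieFrames(mv2))

  # no cells: pure background
  mv0 <- simulateMovie(MovieSpec(heightPx = 32, widthPx = 32, nCells = 0,
                       params = TraceParams(durationS = 10),
                       backgroundNoiseSd = 0), seed = 1)
  expect_true(all(movieFrames(mv0) == 20))

  # too many cells for the frame
  expect_error(simulateMovie(MovieSpec(heightPx = 32, widthPx = 32,
                             nCells = 50,
                             params = TraceParams(durationS = 5)), seed = 1),
               "layout error")
})

test_that("per-cell multipliers preserve expected amplitude across cells", {
  # mean-1 lognormal multipliers: mean peak amplitude over many cells is the
  # configured lognormal mean regardless of the heterogeneity sigmas
  p <- TraceParams(sparkRateHz = 0.1, noiseSigma = 0, waveRateHz = 0)
  amps <- unlist(lapply(1:200, function(s)
    traceMetadata(simulateTrace(p, seed = s))$truth$sparkAmps))
  expected <- exp(p@sparkAmpMu + p@sparkAmpSigma^2 / 2)
  expect_lt(abs(mean(amps) - expected) / expected, 0.1)
})
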