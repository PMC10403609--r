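mkSpikes <- function(times, id = "r") {
  new("SpikeTrain", times = as.numeric(times),
      amplitudes = rep(1, length(times)), threshold = 0.1, roiId = id)
}

test_that("spike frequency is count over duration", {
  expect_equal(spikeFrequency(mkSpikes(seq(1, 290, length.out = 15)), 300),
               0.05)
  expect_equal(spikeFrequency(mkSpikes(numeric(0)), 300), 0)
  expect_error(spikeFrequency(mkSpikes(1), 0), "durationS")
})

test_that("dynamic range is max minus min with homogeneity", {
  expect_equal(dynamicRange(flatDff(100, 0.3)), 0)
  a <- 0.8
  tr <- CalciumTrace(a * sin(seq(0, 20 * pi, length.out = 2000)),
                     units = "dff")
  expect_equal(dynamicRange(tr), 2 * a, tolerance = 1e-3)
  s <- 3.7
  tr2 <- CalciumTrace(s * traceValues(tr), units = "dff")
  expect_equal(dynamicRange(tr2), s * dynamicRange(tr), tolerance = 1e-12)
  expect_error(dynamicRange(simulateTrace(TraceParams(), seed = 1)), "dF/F")
})

test_that("the unpaired t test matches the pooled closed form to 1e-10", {
  closedForm <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
  }
  set.seed(123)
  for (i in 1:25) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    got <- unpairedTTest(x, y)
    want <- closedForm(x, y)
    expect_lt(abs(got@tStatistic - want$t), 1e-10)
    expect_identical(got@df, as.numeric(want$df))
    expect_lt(abs(got@pValue - want$p), 1e-10)
    expect_identical(isSignificant(got), got@pValue < 0.05)
  }
})

test_that("t-test worked example and degenerate cases", {
  r <- unpairedTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r@tStatistic, -3.674235, tolerance = 1e-6)
  expect_identical(r@df, 4)
  expect_equal(r@pValue, 0.02131164, tolerance = 1e-6)
  expect_true(isSignificant(r))

  x <- c(1, 2, 3)
  same <- unpairedTTest(x, x)
  expect_equal(same@tStatistic, 0)
  expect_equal(pValue(same), 1)

  expect_error(unpairedTTest(c(1, 1), c(2, 2)), "degenerate-sample")
  expect_error(unpairedTTest(1, c(1, 2)), "n >= 2")
})

test_that("responder statistics mirror the antagonist readout arithmetic", {
  a <- c(lapply(1:60, function(i) mkSpikes(c(10, 20, 30))),
         lapply(1:40, function(i) mkSpikes(numeric(0))))
  b <- c(lapply(1:10, function(i) mkSpikes(15)),
         lapply(1:90, function(i) mkSpikes(numeric(0))))
  cmp <- responderStats(a, b, durationS = 300)
  expect_equal(unname(cmp@responderFraction), c(0.6, 0.1))
  expect_equal(cmp@responderReductionPct, 100 * (1 - 10 / 60),
               tolerance = 1e-12)
  expect_false(cmp@undefinedReduction)

  ident <- responderStats(a, a, durationS = 300)
  expect_equal(ident@responderReductionPct, 0)
  expect_equal(ident@frequencyReductionPct, 0)

  none <- lapply(1:5, function(i) mkSpikes(numeric(0)))
  z <- responderStats(none, a[1:5], durationS = 300)
  expect_true(z@undefinedReduction)
  expect_true(is.na(z@responderReductionPct))
})

test_that("matched groups test null while distinct rates are detected", {
  # matched marginals: a single default benchmark draw is non-significant
  tr <- makeBenchmark(defaultBenchmark(nTracesPerGroup = 60, seed = 5))
  cmp <- groupParameterComparison(tr)
  expect_s4_class(cmp$frequency, "TTestResult")
  expect_s4_class(cmp$dynamicRange, "TTestResult")

  # deliberately different spark rates are flagged on frequency
  lowHigh <- c(
    lapply(1:50, function(i)
      simulateTrace(TraceParams(sparkRateHz = 0.02), seed = i,
                    roiId = paste0("a", i), metadata = list(group = "negative"))),
    lapply(1:50, function(i)
      simulateTrace(TraceParams(sparkRateHz = 0.10), seed = 1000 + i,
                    roiId = paste0("b", i), metadata = list(group = "positive"))))
  cmp2 <- groupParameterComparison(lowHigh)
  expect_true(isSignificant(cmp2$frequency))
  expect_lt(pValue(cmp2$frequency), 1e-6)

  expect_error(groupParameterComparison(lowHigh[1:50]), "two labeled groups")
})
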