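## classical_stats: spike frequency, dynamic range, unpaired Student's t
## test, responder-fraction summaries, and the two-group parameter
## comparison that mirrors the classical-statistics null result.

#' Spike frequency of a spike train
#'
#' @param spikes a [`SpikeTrain`][SpikeTrain-class].
#' @param durationS recording duration in seconds (> 0).
#' @return Events per second.
#' @examples
#' spikeFrequency(new("SpikeTrain", times = c(1, 10), amplitudes = c(1, 1),
#'                    threshold = 0.1, roiId = "r"), durationS = 300)
#' @export
spikeFrequency <- function(spikes, durationS) {
  if (durationS <= 0) stop("'durationS' must be > 0")
  nSpikes(spikes) / durationS
}

#' Dynamic range of a dF/F trace
#'
#' Defined as `max - min` of the trace (documented convention).
#'
#' @param trace a [CalciumTrace()] in dF/F units.
#' @return Dynamic range in dF/F units.
#' @export
dynamicRange <- function(trace) {
  stopifnot(is(trace, "CalciumTrace"))
  if (trace@units != "dff")
    stop("input error: dynamic range is defined on dF/F traces")
  if (length(trace@values) == 0L) stop("input error: empty trace")
  max(trace@values) - min(trace@values)
}

#' Unpaired Student's t test
#'
#' Classical equal-variance two-sample t test (pooled variance,
#' `df = n1 + n2 - 2`, two-sided p), with Welch's correction available
#' behind a flag. Significance is flagged at alpha = 0.05.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param welch use Welch's unequal-variance test instead.
#' @return A [`TTestResult`][TTestResult-class].
#' @examples
#' unpairedTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
unpairedTTest <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("input error: both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0 && !welch) {
    if (identical(mean(x), mean(y)))
      return(new("TTestResult", tStatistic = 0,
                 df = length(x) + length(y) - 2, pValue = 1,
                 significant = FALSE))
    stop("degenerate-sample error: zero pooled variance")
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  p <- unname(ht$p.value)
  new("TTestResult", tStatistic = unname(ht$statistic),
      df = unname(ht$parameter), pValue = p, significant = p < 0.05)
}

#' Responder fractions and frequency reductions between two conditions
#'
#' A responder is an ROI with at least `minSpikes` detected spikes. Reports
#' per-condition responder fraction and mean spike frequency, plus the
#' percent reduction of each from condition A to condition B,
#' `100 * (1 - b / a)`; reductions are `NA` (with `undefinedReduction`) when
#' the condition-A reference is zero.
#'
#' @param conditionA,conditionB non-empty lists of
#'   [`SpikeTrain`][SpikeTrain-class] objects.
#' @param durationS recording duration, seconds.
#' @param minSpikes responder threshold (default 1).
#' @return A [`ResponderComparison`][ResponderComparison-class].
#' @export
responderStats <- function(conditionA, conditionB, durationS = 300,
                           minSpikes = 1) {
  if (length(conditionA) == 0L || length(conditionB) == 0L)
    stop("input error: both conditions need at least one ROI")
  frac <- function(lst) mean(vapply(lst, nSpikes, integer(1)) >= minSpikes)
  freq <- function(lst) mean(vapply(lst, spikeFrequency, numeric(1),
                                    durationS = durationS))
  fa <- frac(conditionA); fb <- frac(conditionB)
  qa <- freq(conditionA); qb <- freq(conditionB)
  undef <- fa == 0 || qa == 0
  new("ResponderComparison",
      responderFraction = c(a = fa, b = fb),
      meanFrequencyHz = c(a = qa, b = qb),
      responderReductionPct = if (fa > 0) 100 * (1 - fb / fa) else NA_real_,
      frequencyReductionPct = if (qa > 0) 100 * (1 - qb / qa) else NA_real_,
      undefinedReduction = undef)
}

#' Compare classical waveform parameters between benchmark groups
#'
#' Runs unpaired Student's t tests on per-trace spike frequency and on
#' per-trace dynamic range between the two labeled groups of a benchmark.
#' On the matched-marginal benchmark both tests are expected to be
#' non-significant even when an image classifier separates the groups.
#'
#' @param traces list of [CalciumTrace()] with `group` metadata labels.
#' @param detections optional list of [`SpikeTrain`][SpikeTrain-class]
#'   aligned with `traces`; detected with defaults when missing.
#' @return A list with [`TTestResult`][TTestResult-class] elements
#'   `frequency` and `dynamicRange`, and the per-group means under `means`.
#' @examples
#' \donttest{
#' tr <- makeBenchmark(defaultBenchmark(nTracesPerGroup = 20, seed = 1))
#' cmp <- groupParameterComparison(tr)
#' pValue(cmp$frequency)
#' }
#' @export
groupParameterComparison <- function(traces, detections = NULL) {
  groups <- vapply(traces, function(x) x@metadata$group, character(1))
  lv <- sort(unique(groups))
  if (length(lv) != 2L)
    stop("input error: exactly two labeled groups are required")
  if (any(table(groups) < 2L))
    stop("input error: each group needs >= 2 traces")
  noise <- lapply(traces, estimateNoise)
  if (is.null(detections))
    detections <- mapply(detectSpikes, traces, noise, SIMPLIFY = FALSE)

  durationS <- vapply(traces, function(x)
    length(x@values) * x@frameIntervalS, numeric(1))
  freq <- mapply(spikeFrequency, detections, durationS)
  dr <- vapply(mapply(dffTrace, traces, noise, SIMPLIFY = FALSE),
               dynamicRange, numeric(1))

  a <- groups == lv[1]
  list(frequency = unpairedTTest(freq[a], freq[!a]),
       dynamicRange = unpairedTTest(dr[a], dr[!a]),
       means = list(frequencyHz = tapply(freq, groups, mean),
                    dynamicRange = tapply(dr, groups, mean)))
}
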