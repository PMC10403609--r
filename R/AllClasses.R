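#' @import methods
NULL

## ---------------------------------------------------------------------------
## Simulation parameter classes
## ---------------------------------------------------------------------------

#' Parameters of a simulated calcium trace
#'
#' `TraceParams` parameterizes the phenomenological trace model: a Poisson
#' train of fast calcium sparks (difference-of-exponentials templates with
#' rise much shorter than decay, lognormal peak amplitudes), a sparse train of
#' slow half-sine calcium waves, i.i.d. Gaussian sensor noise, and a constant
#' fluorescence baseline. Per-cell lognormal multipliers model between-cell
#' heterogeneity of amplitude scale (`cellAmpSigma`) and of spark kinetics
#' (`cellTauSigma`); both multipliers have mean 1 so expected rate and
#' expected amplitude do not depend on them.
#'
#' `effectKnob` in \[0, 1\] encodes a treatment-dependent kinetic shift: it
#' rescales the mean spark decay and rise time constants (see
#' [simulateTrace()]) while leaving the event rate and the peak-amplitude
#' distribution untouched, so spike frequency and dynamic range stay matched
#' between treated and untreated populations by construction.
#'
#' @param durationS recording length in seconds (default 300 s, i.e. 5 min).
#' @param frameIntervalS sampling interval in seconds (default 1 s).
#' @param sparkRateHz Poisson intensity of spark events, events/s.
#' @param sparkAmpMu,sparkAmpSigma lognormal meanlog/sdlog of per-event peak
#'   amplitude in dF/F units.
#' @param sparkRiseS,sparkDecayS spark rise and decay time constants, seconds
#'   (rise << decay).
#' @param cellAmpSigma sdlog of the per-cell lognormal amplitude multiplier.
#' @param cellTauSigma sdlog of the per-cell lognormal kinetics multiplier.
#' @param waveRateHz Poisson intensity of slow calcium waves, events/s.
#' @param waveAmp peak amplitude of a wave, dF/F units.
#' @param waveDurationS duration of the half-sine wave template, seconds.
#' @param noiseSigma Gaussian sensor noise s.d., dF/F units.
#' @param baselineF0 baseline fluorescence, arbitrary units.
#' @param effectKnob dimensionless treatment-effect strength in \[0, 1\].
#' @return A `TraceParams` object.
#' @seealso [simulateTrace()], [BenchmarkSpec()]
#' @examples
#' p <- TraceParams(sparkRateHz = 0.05)
#' sparkRate(p)
#' @export
TraceParams <- function(durationS = 300,
                        frameIntervalS = 1,
                        sparkRateHz = 0.04,
                        sparkAmpMu = log(1.0),
                        sparkAmpSigma = 0.22,
                        sparkRiseS = 0.6,
                        sparkDecayS = 2.5,
                        cellAmpSigma = 0.22,
                        cellTauSigma = 0.15,
                        waveRateHz = 1 / 300,
                        waveAmp = 0.25,
                        waveDurationS = 60,
                        noiseSigma = 0.03,
                        baselineF0 = 100,
                        effectKnob = 0) {
  new("TraceParams",
      durationS = as.numeric(durationS),
      frameIntervalS = as.numeric(frameIntervalS),
      sparkRateHz = as.numeric(sparkRateHz),
      sparkAmpMu = as.numeric(sparkAmpMu),
      sparkAmpSigma = as.numeric(sparkAmpSigma),
      sparkRiseS = as.numeric(sparkRiseS),
      sparkDecayS = as.numeric(sparkDecayS),
      cellAmpSigma = as.numeric(cellAmpSigma),
      cellTauSigma = as.numeric(cellTauSigma),
      waveRateHz = as.numeric(waveRateHz),
      waveAmp = as.numeric(waveAmp),
      waveDurationS = as.numeric(waveDurationS),
      noiseSigma = as.numeric(noiseSigma),
      baselineF0 = as.numeric(baselineF0),
      effectKnob = as.numeric(effectKnob))
}

setClass("TraceParams",
  representation(durationS = "numeric", frameIntervalS = "numeric",
                 sparkRateHz = "numeric", sparkAmpMu = "numeric",
                 sparkAmpSigma = "numeric", sparkRiseS = "numeric",
                 sparkDecayS = "numeric", cellAmpSigma = "numeric",
                 cellTauSigma = "numeric", waveRateHz = "numeric",
                 waveAmp = "numeric", waveDurationS = "numeric",
                 noiseSigma = "numeric", baselineF0 = "numeric",
                 effectKnob = "numeric"),
  validity = function(object) {
    msg <- character()
    chk1 <- function(x, nm) if (length(slot(object, nm)) != 1L ||
                                !is.finite(slot(object, nm)))
      paste0("'", nm, "' must be a single finite number") else NULL
    for (nm in slotNames(object)) {
      m <- chk1(slot(object, nm), nm)
      if (!is.null(m)) msg <- c(msg, m)
    }
    if (length(msg)) return(msg)
    if (object@durationS <= 0) msg <- c(msg, "'durationS' must be > 0")
    if (object@frameIntervalS <= 0) msg <- c(msg, "'frameIntervalS' must be > 0")
    for (nm in c("sparkRateHz", "waveRateHz"))
      if (slot(object, nm) < 0) msg <- c(msg, paste0("'", nm, "' must be >= 0"))
    for (nm in c("sparkAmpSigma", "cellAmpSigma", "cellTauSigma", "noiseSigma"))
      if (slot(object, nm) < 0) msg <- c(msg, paste0("'", nm, "' must be >= 0"))
    for (nm in c("sparkRiseS", "sparkDecayS", "waveDurationS", "baselineF0"))
      if (slot(object, nm) <= 0) msg <- c(msg, paste0("'", nm, "' must be > 0"))
    if (object@sparkRiseS >= object@sparkDecayS)
      msg <- c(msg, "'sparkRiseS' must be < 'sparkDecayS'")
    if (object@effectKnob < 0 || object@effectKnob > 1)
      msg <- c(msg, "'effectKnob' must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Specification of a two-group waveform benchmark
#'
#' A benchmark holds one `TraceParams` per treatment group. The two parameter
#' sets must be identical except for `effectKnob`, so that by construction the
#' groups share the same spark rate and amplitude distribution (spike
#' frequency and dynamic range are matched marginals) and differ only in
#' waveform kinetics.
#'
#' @param nTracesPerGroup number of traces simulated per group.
#' @param negativeParams,positiveParams [TraceParams()] for the two groups,
#'   identical except in their `effectKnob` slot.
#' @param seed integer seed; every downstream draw derives from it.
#' @param substances optional 2-element character vector of substance labels
#'   attached as metadata (e.g. `c("caffeine-low", "caffeine-high")`).
#' @return A `BenchmarkSpec` object.
#' @seealso [makeBenchmark()], [defaultBenchmark()]
#' @export
BenchmarkSpec <- function(nTracesPerGroup = 100,
                          negativeParams = TraceParams(effectKnob = 0),
                          positiveParams = TraceParams(effectKnob = 0.6),
                          seed = 1L,
                          substances = c("none", "caffeine-high")) {
  new("BenchmarkSpec",
      nTracesPerGroup = as.integer(nTracesPerGroup),
      negativeParams = negativeParams,
      positiveParams = positiveParams,
      seed = as.integer(seed),
      substances = as.character(substances))
}

setClass("BenchmarkSpec",
  representation(nTracesPerGroup = "integer",
                 negativeParams = "TraceParams",
                 positiveParams = "TraceParams",
                 seed = "integer",
                 substances = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nTracesPerGroup < 1L)
      msg <- c(msg, "'nTracesPerGroup' must be >= 1")
    other <- setdiff(slotNames(object@negativeParams), "effectKnob")
    for (nm in other)
      if (!identical(slot(object@negativeParams, nm),
                     slot(object@positiveParams, nm)))
        msg <- c(msg, paste0("group TraceParams may differ only in ",
                             "'effectKnob' (found difference in '", nm, "')"))
    if (length(object@substances) != 2L)
      msg <- c(msg, "'substances' must have length 2")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic fluorescence movie
#'
#' Describes the imaging geometry (default 512 x 512 px at 1 um/px, matching
#' a 1 frame/s widefield recording) and the simulated field: `nCells`
#' disk-shaped cells placed on a jittered grid so footprints never overlap,
#' each driven by its own simulated calcium trace.
#'
#' @param heightPx,widthPx frame dimensions in pixels.
#' @param pixelSizeUm physical pixel size, micrometres/pixel.
#' @param nCells number of cells placed in the field.
#' @param cellRadiusUm cell footprint radius, micrometres.
#' @param params per-cell [TraceParams()].
#' @param backgroundLevel background fluorescence, same units as `baselineF0`.
#' @param backgroundNoiseSd per-pixel Gaussian noise s.d. (intensity units).
#' @return A `MovieSpec` object.
#' @seealso [simulateMovie()]
#' @export
MovieSpec <- function(heightPx = 512, widthPx = 512, pixelSizeUm = 1,
                      nCells = 16, cellRadiusUm = 7,
                      params = TraceParams(),
                      backgroundLevel = 20, backgroundNoiseSd = 1) {
  new("MovieSpec", heightPx = as.integer(heightPx),
      widthPx = as.integer(widthPx), pixelSizeUm = as.numeric(pixelSizeUm),
      nCells = as.integer(nCells), cellRadiusUm = as.numeric(cellRadiusUm),
      params = params, backgroundLevel = as.numeric(backgroundLevel),
      backgroundNoiseSd = as.numeric(backgroundNoiseSd))
}

setClass("MovieSpec",
  representation(heightPx = "integer", widthPx = "integer",
                 pixelSizeUm = "numeric", nCells = "integer",
                 cellRadiusUm = "numeric", params = "TraceParams",
                 backgroundLevel = "numeric", backgroundNoiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@heightPx <= 0L || object@widthPx <= 0L)
      msg <- c(msg, "frame dimensions must be > 0")
    if (object@pixelSizeUm <= 0) msg <- c(msg, "'pixelSizeUm' must be > 0")
    if (object@nCells < 0L) msg <- c(msg, "'nCells' must be >= 0")
    if (object@cellRadiusUm <= 0) msg <- c(msg, "'cellRadiusUm' must be > 0")
    if (object@backgroundNoiseSd < 0)
      msg <- c(msg, "'backgroundNoiseSd' must be >= 0")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' One ROI's calcium fluorescence time series
#'
#' Holds the sampled fluorescence signal F(t) of a single region of interest
#' together with its calibration (frame interval) and unit flag: `"raw"` for
#' fluorescence in camera units, `"dff"` for the dimensionless normalized
#' signal dF/F = (F - F0)/F0.
#'
#' @param values numeric vector of samples.
#' @param frameIntervalS sampling interval, seconds.
#' @param units `"raw"` or `"dff"`.
#' @param roiId identifier string.
#' @param metadata named list (group/substance/dose/lot labels, simulation
#'   ground truth, ...).
#' @return A `CalciumTrace` object.
#' @export
CalciumTrace <- function(values, frameIntervalS = 1, units = c("raw", "dff"),
                         roiId = "roi", metadata = list()) {
  units <- match.arg(units)
  new("CalciumTrace", values = as.numeric(values),
      frameIntervalS = as.numeric(frameIntervalS), units = units,
      roiId = as.character(roiId), metadata = metadata)
}

setClass("CalciumTrace",
  representation(values = "numeric", frameIntervalS = "numeric",
                 units = "character", roiId = "character",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) < 2L)
      msg <- c(msg, "'values' must have length >= 2")
    if (length(object@frameIntervalS) != 1L || object@frameIntervalS <= 0)
      msg <- c(msg, "'frameIntervalS' must be a single value > 0")
    if (!object@units %in% c("raw", "dff"))
      msg <- c(msg, "'units' must be \"raw\" or \"dff\"")
    if (length(msg)) msg else TRUE
  })

#' A grayscale fluorescence time-lapse movie
#'
#' Frames are stored as a numeric `H x W x T` array (`frames`); accessors
#' report the frame count and shape. `metadata` carries simulation ground
#' truth when the movie was generated by [simulateMovie()].
#'
#' @param frames numeric array, dimensions height x width x frames.
#' @param pixelSizeUm physical pixel size, micrometres/pixel.
#' @param frameIntervalS frame interval, seconds.
#' @param metadata named list.
#' @return A `FluorescenceMovie` object.
#' @export
FluorescenceMovie <- function(frames, pixelSizeUm = 1, frameIntervalS = 1,
                              metadata = list()) {
  new("FluorescenceMovie", frames = frames,
      pixelSizeUm = as.numeric(pixelSizeUm),
      frameIntervalS = as.numeric(frameIntervalS), metadata = metadata)
}

setClass("FluorescenceMovie",
  representation(frames = "array", pixelSizeUm = "numeric",
                 frameIntervalS = "numeric", metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "'frames' must be a 3-d array (height, width, frames)")
    if (object@pixelSizeUm <= 0) msg <- c(msg, "'pixelSizeUm' must be > 0")
    if (object@frameIntervalS <= 0) msg <- c(msg, "'frameIntervalS' must be > 0")
    if (length(msg)) msg else TRUE
  })

#' A hexagonal ROI tiling of an imaging frame
#'
#' Produced by [hexTiling()]. `labels` is an integer matrix with the frame's
#' shape; entry 0 marks pixels outside every complete hexagon, entry k > 0
#' assigns the pixel to ROI k. `centers` holds ROI centres in pixel
#' coordinates (0-based row/col).
#'
#' @slot labels integer label matrix (H x W).
#' @slot centers numeric matrix, one row per ROI, columns `row`, `col`.
#' @slot diameterUm hexagon across-corners diameter, micrometres.
#' @slot pixelSizeUm pixel size, micrometres/pixel.
#' @export
setClass("HexROISet",
  representation(labels = "matrix", centers = "matrix",
                 diameterUm = "numeric", pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@centers) > 0 && max(object@labels) > nrow(object@centers))
      msg <- c(msg, "label matrix references more ROIs than centers")
    if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Baseline and noise estimate of a fluorescence trace
#'
#' `f0` is the robust baseline fluorescence F0 (running low-percentile
#' summary) and `sigma` the Gaussian noise scale fitted to baseline-side
#' residuals; both are in the units of the trace they were estimated from.
#'
#' @slot f0 baseline fluorescence.
#' @slot sigma Gaussian noise scale, >= 0.
#' @slot units units of the source trace (`"raw"` or `"dff"`).
#' @export
setClass("NoiseEstimate",
  representation(f0 = "numeric", sigma = "numeric", units = "character"),
  validity = function(object) {
    if (object@sigma < 0) "'sigma' must be >= 0" else TRUE
  })

#' Detected spikes of one trace
#'
#' @slot times spike times in seconds, strictly increasing.
#' @slot amplitudes detrended dF/F amplitude at each spike.
#' @slot threshold the k*sigma detection threshold used (dF/F units).
#' @slot roiId source ROI identifier.
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", amplitudes = "numeric",
                 threshold = "numeric", roiId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@amplitudes))
      msg <- c(msg, "'times' and 'amplitudes' lengths differ")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "'times' must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Rendering / composites
## ---------------------------------------------------------------------------

#' Configuration of the waveform rasterizer
#'
#' The y axis is a *global fixed* dF/F range shared by every rendered image,
#' so that amplitude differences between traces remain visible in the rasters
#' (per-trace autoscaling would erase exactly the dynamic-range variability
#' the composite method is designed to dilute). No axes or ticks are drawn.
#'
#' @param canvasPx canvas (height, width) in pixels; at least (32, 32).
#' @param yRangeDff global dF/F axis range `c(lo, hi)`.
#' @param lineWidthPx stroke thickness in pixels.
#' @param background,foreground gray levels in \[0, 1\].
#' @param axesDrawn reserved; only `FALSE` (bare plots) is supported.
#' @return A `RenderConfig` object.
#' @seealso [renderWaveform()]
#' @export
RenderConfig <- function(canvasPx = c(224, 224), yRangeDff = c(-0.5, 4),
                         lineWidthPx = 1, background = 0, foreground = 1,
                         axesDrawn = FALSE) {
  new("RenderConfig", canvasPx = as.integer(canvasPx),
      yRangeDff = as.numeric(yRangeDff), lineWidthPx = as.integer(lineWidthPx),
      background = as.numeric(background), foreground = as.numeric(foreground),
      axesDrawn = as.logical(axesDrawn))
}

setClass("RenderConfig",
  representation(canvasPx = "integer", yRangeDff = "numeric",
                 lineWidthPx = "integer", background = "numeric",
                 foreground = "numeric", axesDrawn = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@canvasPx) != 2L || any(object@canvasPx < 32L))
      msg <- c(msg, "'canvasPx' must be two values >= 32")
    if (length(object@yRangeDff) != 2L ||
        object@yRangeDff[1] >= object@yRangeDff[2])
      msg <- c(msg, "'yRangeDff' must satisfy lo < hi")
    if (object@lineWidthPx < 1L) msg <- c(msg, "'lineWidthPx' must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' A rasterized waveform image
#'
#' @slot pixels numeric matrix in \[0, 1\], dimensions = render canvas.
#' @slot roiId source trace identifier.
#' @slot group group label (`"negative"`, `"positive"` or `"unknown"`).
#' @slot metadata named list (substance, dose, lot, clipping fraction, ...).
#' @slot configHash hash of the [RenderConfig()] used.
#' @export
setClass("WaveformImage",
  representation(pixels = "matrix", roiId = "character", group = "character",
                 metadata = "list", configHash = "character"))

#' A 3 x 3 composite of nine waveform images
#'
#' @slot pixels numeric matrix, 3 x tile height by 3 x tile width.
#' @slot memberIds the nine distinct member waveform-image ids.
#' @slot group common group label of the members.
#' @slot seed the sampling seed recorded for this composite.
#' @export
setClass("CompositeImage",
  representation(pixels = "matrix", memberIds = "character",
                 group = "character", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@memberIds) != 9L)
      msg <- c(msg, "a composite must have exactly 9 member ids")
    if (anyDuplicated(object@memberIds))
      msg <- c(msg, "member ids must be distinct")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Learning / evaluation
## ---------------------------------------------------------------------------

#' A train-validation / test split assignment
#'
#' @slot tags character vector, one of `"trainval"`/`"test"` per image.
#' @slot fractions the target fractions (trainval, test).
#' @slot seed split seed.
#' @slot stratified whether the split was stratified by group.
#' @export
setClass("SplitAssignment",
  representation(tags = "character", fractions = "numeric", seed = "integer",
                 stratified = "logical"),
  validity = function(object) {
    if (!all(object@tags %in% c("trainval", "test")))
      "tags must be \"trainval\" or \"test\"" else TRUE
  })

#' A trained binary waveform-image classifier
#'
#' Wraps the fitted backend (a probability random forest on deterministic
#' raster features: pooled pixel grid plus row-profile ink/run/stroke-width
#' statistics) with everything needed to reproduce its predictions: the
#' featurization options, class labels, seed and a hash of the training
#' config.
#'
#' @slot fit the fitted backend object.
#' @slot classes the two class labels, negative class first.
#' @slot featureOpts featurization options (grid, row bands, width levels).
#' @slot tileRows raster rows of one waveform tile at training time.
#' @slot seed training seed.
#' @slot configHash hash of the training configuration.
#' @export
setClass("ClassifierModel",
  representation(fit = "ANY", classes = "character", featureOpts = "list",
                 tileRows = "integer", seed = "integer",
                 configHash = "character"))

#' Classifier evaluation report
#'
#' `averagePrecision` is the unweighted mean of the two per-class precisions
#' (argmax predictions); `prAuc` additionally reports the area under the
#' precision-recall curve of the positive-class score for transparency.
#'
#' @slot confusion 2 x 2 integer matrix, rows = truth, cols = prediction.
#' @slot precision,recall named per-class vectors.
#' @slot averagePrecision mean of the two class precisions.
#' @slot prAuc area under the positive-class precision-recall curve.
#' @slot nTest number of test images.
#' @slot degenerate classes never predicted (their precision is reported 0).
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", precision = "numeric",
                 recall = "numeric", averagePrecision = "numeric",
                 prAuc = "numeric", nTest = "integer",
                 degenerate = "character"))

#' Voting segregation of an untrained substance
#'
#' @slot substance substance label.
#' @slot nImages number of images predicted.
#' @slot nPredictedPositive how many were assigned to the positive class.
#' @slot fractionPositive `nPredictedPositive / nImages`.
#' @export
setClass("SegregationResult",
  representation(substance = "character", nImages = "integer",
                 nPredictedPositive = "integer", fractionPositive = "numeric"),
  validity = function(object) {
    if (object@fractionPositive < 0 || object@fractionPositive > 1)
      "'fractionPositive' must be in [0, 1]" else TRUE
  })

## ---------------------------------------------------------------------------
## Classical statistics
## ---------------------------------------------------------------------------

#' Unpaired Student's t-test result
#'
#' @slot tStatistic the t statistic.
#' @slot df degrees of freedom (n1 + n2 - 2 for the pooled test).
#' @slot pValue two-sided p value.
#' @slot significant `TRUE` iff p < 0.05.
#' @export
setClass("TTestResult",
  representation(tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 significant = "logical"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1)
      "'pValue' must be in [0, 1]" else TRUE
  })

#' Responder-fraction comparison between two conditions
#'
#' Mirrors the antagonist-type readout: the fraction of ROIs with at least
#' `minSpikes` detected spikes per condition, the mean spike frequency, and
#' the percent reduction of each from condition A to condition B
#' (100 x (1 - b/a)). Reductions are `NA` with `undefinedReduction = TRUE`
#' when the reference quantity is zero.
#'
#' @slot responderFraction named numeric, conditions `a` and `b`.
#' @slot meanFrequencyHz named numeric, conditions `a` and `b`.
#' @slot responderReductionPct percent reduction in responder fraction.
#' @slot frequencyReductionPct percent reduction in mean frequency.
#' @slot undefinedReduction flag set when a reference quantity was zero.
#' @export
setClass("ResponderComparison",
  representation(responderFraction = "numeric", meanFrequencyHz = "numeric",
                 responderReductionPct = "numeric",
                 frequencyReductionPct = "numeric",
                 undefinedReduction = "logical"))
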