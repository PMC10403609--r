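#' @include AllClasses.R
NULL

#' Accessors for CaSparkML objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `traceValues`/`traceUnits`/`frameInterval`/`roiId` for [CalciumTrace()],
#' `movieFrames`/`nFrames` for [FluorescenceMovie()], `roiLabels`/`roiCenters`
#' /`nRois` for `HexROISet`, `spikeTimes`/`spikeAmplitudes` for `SpikeTrain`,
#' `imagePixels`/`imageGroup` for the image classes, `sparkRate` for
#' [TraceParams()], and `averagePrecision`/`classPrecision`/`classRecall`/
#' `confusionMatrix` for `EvalReport`.
#'
#' @param x an object of the matching class.
#' @return The slot value (see each method).
#' @name accessors
#' @aliases traceValues traceUnits frameInterval roiId movieFrames nFrames
#'   roiLabels roiCenters nRois spikeTimes spikeAmplitudes imagePixels
#'   imageGroup sparkRate averagePrecision classPrecision classRecall
#'   confusionMatrix
#' @examples
#' tr <- CalciumTrace(c(1, 2, 3), frameIntervalS = 1)
#' traceValues(tr)
NULL

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "CalciumTrace", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))
#' @rdname accessors
#' @export
setMethod("traceUnits", "CalciumTrace", function(x) x@units)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "CalciumTrace", function(x) x@frameIntervalS)
#' @rdname accessors
#' @export
setMethod("frameInterval", "FluorescenceMovie", function(x) x@frameIntervalS)

#' @rdname accessors
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))
#' @rdname accessors
#' @export
setMethod("roiId", "CalciumTrace", function(x) x@roiId)
#' @rdname accessors
#' @export
setMethod("roiId", "SpikeTrain", function(x) x@roiId)

#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))
#' @rdname accessors
#' @export
setMethod("traceMetadata", "CalciumTrace", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("movieFrames", function(x) standardGeneric("movieFrames"))
#' @rdname accessors
#' @export
setMethod("movieFrames", "FluorescenceMovie", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FluorescenceMovie", function(x) dim(x@frames)[3L])

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setMethod("roiLabels", "HexROISet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("roiCenters", function(x) standardGeneric("roiCenters"))
#' @rdname accessors
#' @export
setMethod("roiCenters", "HexROISet", function(x) x@centers)

#' @rdname accessors
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))
#' @rdname accessors
#' @export
setMethod("nRois", "HexROISet", function(x) nrow(x@centers))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("spikeAmplitudes", function(x) standardGeneric("spikeAmplitudes"))
#' @rdname accessors
#' @export
setMethod("spikeAmplitudes", "SpikeTrain", function(x) x@amplitudes)

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setMethod("imagePixels", "WaveformImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("imagePixels", "CompositeImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("imageGroup", function(x) standardGeneric("imageGroup"))
#' @rdname accessors
#' @export
setMethod("imageGroup", "WaveformImage", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("imageGroup", "CompositeImage", function(x) x@group)

#' @rdname accessors
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))
#' @rdname accessors
#' @export
setMethod("memberIds", "CompositeImage", function(x) x@memberIds)

#' @rdname accessors
#' @export
setGeneric("sparkRate", function(x) standardGeneric("sparkRate"))
#' @rdname accessors
#' @export
setMethod("sparkRate", "TraceParams", function(x) x@sparkRateHz)

#' @rdname accessors
#' @export
setGeneric("averagePrecision", function(x) standardGeneric("averagePrecision"))
#' @rdname accessors
#' @export
setMethod("averagePrecision", "EvalReport", function(x) x@averagePrecision)

#' @rdname accessors
#' @export
setGeneric("classPrecision", function(x) standardGeneric("classPrecision"))
#' @rdname accessors
#' @export
setMethod("classPrecision", "EvalReport", function(x) x@precision)

#' @rdname accessors
#' @export
setGeneric("classRecall", function(x) standardGeneric("classRecall"))
#' @rdname accessors
#' @export
setMethod("classRecall", "EvalReport", function(x) x@recall)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setGeneric("fractionPositive", function(x) standardGeneric("fractionPositive"))
#' @rdname accessors
#' @export
setMethod("fractionPositive", "SegregationResult",
          function(x) x@fractionPositive)

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "TTestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))
#' @rdname accessors
#' @export
setMethod("isSignificant", "TTestResult", function(x) x@significant)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf("CalciumTrace '%s': %d samples @ %.3g s (%s units)\n",
              object@roiId, length(object@values), object@frameIntervalS,
              object@units))
})

setMethod("show", "FluorescenceMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FluorescenceMovie: %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
              d[3], d[1], d[2], object@pixelSizeUm, object@frameIntervalS))
})

setMethod("show", "HexROISet", function(object) {
  cat(sprintf("HexROISet: %d hexagonal ROIs (%.3g um across corners) on a %d x %d frame\n",
              nrow(object@centers), object@diameterUm,
              nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes (threshold %.3g dF/F)\n",
              object@roiId, length(object@times), object@threshold))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: n_test = %d, average precision = %.3f (PR-AUC %.3f)\n",
              object@nTest, object@averagePrecision, object@prAuc))
  cat("  precision:", paste(sprintf("%s %.3f", names(object@precision),
                                    object@precision), collapse = ", "), "\n")
  cat("  recall:   ", paste(sprintf("%s %.3f", names(object@recall),
                                    object@recall), collapse = ", "), "\n")
  if (length(object@degenerate))
    cat("  degenerate (never predicted):",
        paste(object@degenerate, collapse = ", "), "\n")
})

setMethod("show", "SegregationResult", function(object) {
  cat(sprintf("SegregationResult '%s': %d/%d images voted positive (%.1f%%)\n",
              object@substance, object@nPredictedPositive, object@nImages,
              100 * object@fractionPositive))
})

setMethod("show", "TTestResult", function(object) {
  cat(sprintf("Unpaired t test: t = %.4g, df = %.4g, p = %.4g (%s at alpha 0.05)\n",
              object@tStatistic, object@df, object@pValue,
              if (object@significant) "significant" else "not significant"))
})

setMethod("show", "TraceParams", function(object) {
  cat(sprintf("TraceParams: %.0f s @ %.3g s/frame, spark rate %.3g Hz, effect knob %.2f\n",
              object@durationS, object@frameIntervalS, object@sparkRateHz,
              object@effectKnob))
})
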