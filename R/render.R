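## render: rasterize dF/F traces into fixed-size grayscale waveform images.
##
## The rasterizer is deterministic and device-free: time maps linearly onto
## the x axis and each pixel column is filled between the minimum and maximum
## of the piecewise-linear trace over that column (the classic min-max
## waveform raster), so the rendered vertical extent is an exact, monotone
## image of the trace's amplitude under the global fixed y axis.

#' Rasterize a calcium trace into a waveform image
#'
#' Time is mapped linearly across the full canvas width; dF/F is mapped by
#' the *global fixed* `yRangeDff` of the [RenderConfig()] (no per-trace
#' autoscaling, so amplitude differences between traces stay visible).
#' Values outside the range are clipped and the clipped fraction is recorded
#' in the image metadata (a warning is emitted above 1%). The stroke is
#' thickened vertically to `lineWidthPx`.
#'
#' @param trace a [CalciumTrace()] in dF/F units (see [dffTrace()]).
#' @param cfg a [RenderConfig()].
#' @return A [`WaveformImage`][WaveformImage-class]; pixels are a
#'   `canvasPx[1] x canvasPx[2]` matrix in `[0, 1]` with row 1 = top.
#' @examples
#' tr <- dffTrace(simulateTrace(TraceParams(), seed = 1))
#' img <- renderWaveform(tr, RenderConfig(canvasPx = c(64, 64)))
#' dim(imagePixels(img))
#' @export
renderWaveform <- function(trace, cfg = RenderConfig()) {
  stopifnot(is(trace, "CalciumTrace"), is(cfg, "RenderConfig"))
  validObject(cfg)
  if (trace@units != "dff")
    stop("input error: trace must be in dF/F units (see dffTrace)")
  v <- trace@values
  if (length(v) < 2L) stop("input error: empty trace")

  h <- cfg@canvasPx[1]; w <- cfg@canvasPx[2]
  lo <- cfg@yRangeDff[1]; hi <- cfg@yRangeDff[2]
  clipFrac <- mean(v < lo | v > hi)
  if (clipFrac > 0.01)
    warning(sprintf("%.1f%% of samples clipped by yRangeDff in %s",
                    100 * clipFrac, trace@roiId))
  v <- pmin(pmax(v, lo), hi)

  n <- length(v)
  x <- (seq_len(n) - 1) / (n - 1) * (w - 1)        # sample x positions
  colOf <- pmin(floor(x + 0.5), w - 1) + 1L        # column of each sample

  ## per-column min/max over samples falling in the column
  colMin <- rep(NA_real_, w); colMax <- rep(NA_real_, w)
  agg <- tapply(v, colOf, range)
  ix <- as.integer(names(agg))
  colMin[ix] <- vapply(agg, `[`, numeric(1), 1L)
  colMax[ix] <- vapply(agg, `[`, numeric(1), 2L)

  ## interpolated values at the column boundaries keep adjacent columns
  ## connected (and cover columns with no sample)
  bx <- seq(0.5, w - 1.5, by = 1)
  if (length(bx)) {
    bv <- stats::approx(x, v, xout = bx, rule = 2)$y
    lix <- floor(bx) + 1L              # boundary belongs to both neighbours
    rix <- lix + 1L
    colMin[lix] <- pmin(colMin[lix], bv, na.rm = TRUE)
    colMax[lix] <- pmax(colMax[lix], bv, na.rm = TRUE)
    colMin[rix] <- pmin(colMin[rix], bv, na.rm = TRUE)
    colMax[rix] <- pmax(colMax[rix], bv, na.rm = TRUE)
  }
  colMin[is.na(colMin)] <- v[1]; colMax[is.na(colMax)] <- v[1]

  ## map dF/F to rows (row 1 = top = hi)
  rowOf <- function(y) pmin(pmax(round((hi - y) / (hi - lo) * (h - 1)), 0), h - 1) + 1L
  rTop <- rowOf(colMax); rBot <- rowOf(colMin)
  half <- (cfg@lineWidthPx - 1L) %/% 2L
  extra <- cfg@lineWidthPx - 1L - half
  rTop <- pmax(rTop - half, 1L); rBot <- pmin(rBot + extra, h)

  pix <- matrix(cfg@background, h, w)
  lens <- rBot - rTop + 1L
  rows <- sequence(lens) - 1L + rep(rTop, lens)
  cols <- rep(seq_len(w), lens)
  pix[cbind(rows, cols)] <- cfg@foreground

  new("WaveformImage", pixels = pix, roiId = trace@roiId,
      group = if (is.null(trace@metadata$group)) "unknown"
              else trace@metadata$group,
      metadata = list(substance = trace@metadata$substance,
                      clippedFraction = clipFrac),
      configHash = configHash(cfg))
}

#' Render a list of dF/F traces
#'
#' Convenience vectorization of [renderWaveform()].
#'
#' @param traces list of [CalciumTrace()] in dF/F units.
#' @param cfg a [RenderConfig()].
#' @return List of [`WaveformImage`][WaveformImage-class].
#' @export
renderWaveforms <- function(traces, cfg = RenderConfig()) {
  lapply(traces, renderWaveform, cfg = cfg)
}
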