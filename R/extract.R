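## roi_extract: movie -> per-ROI waveforms.
## Preprocessing, hexagonal tiling, trace extraction, baseline/noise
## estimation, and spike detection with a slow-baseline ("slow dynamic")
## threshold mode.

#' Contrast-enhance and smooth a fluorescence movie
#'
#' Applies a linear contrast stretch between the global `lo`/`hi` intensity
#' percentiles (values outside are clipped; the stretched range is mapped back
#' onto the movie's original global min/max so percentiles `(0, 100)` are the
#' identity) followed by per-frame spatial Gaussian smoothing.
#'
#' @param movie a [FluorescenceMovie()].
#' @param contrastPercentiles `c(lo, hi)` percentiles, `0 <= lo < hi <= 100`.
#' @param smoothSigmaPx Gaussian smoothing sigma in pixels (0 = none).
#' @return A [FluorescenceMovie()] with the same shape and metadata.
#' @examples
#' mv <- simulateMovie(MovieSpec(heightPx = 48, widthPx = 48, nCells = 1,
#'                     params = TraceParams(durationS = 10)), seed = 1)
#' pp <- preprocessMovie(mv, c(1, 99), smoothSigmaPx = 1)
#' @export
preprocessMovie <- function(movie, contrastPercentiles = c(1, 99),
                            smoothSigmaPx = 1) {
  stopifnot(is(movie, "FluorescenceMovie"))
  lo <- contrastPercentiles[1]; hi <- contrastPercentiles[2]
  if (!(lo >= 0 && lo < hi && hi <= 100))
    stop("contrastPercentiles must satisfy 0 <= lo < hi <= 100")
  if (smoothSigmaPx < 0) stop("'smoothSigmaPx' must be >= 0")
  arr <- movie@frames
  if (length(arr) == 0L) stop("input error: empty movie")

  rng <- range(arr)
  if (rng[1] < rng[2]) {
    q <- stats::quantile(arr, c(lo, hi) / 100, names = FALSE)
    if (q[1] < q[2]) {
      arr <- pmin(pmax(arr, q[1]), q[2])
      arr <- (arr - q[1]) / (q[2] - q[1]) * (rng[2] - rng[1]) + rng[1]
      dim(arr) <- dim(movie@frames)
    }
  }
  if (smoothSigmaPx > 0)
    for (f in seq_len(dim(arr)[3]))
      arr[, , f] <- gaussBlur(arr[, , f], smoothSigmaPx)

  FluorescenceMovie(arr, pixelSizeUm = movie@pixelSizeUm,
                    frameIntervalS = movie@frameIntervalS,
                    metadata = movie@metadata)
}

## centers of a flat-top hexagonal lattice covering (and overhanging) a frame;
## R = circumradius in px. Columns spaced 1.5 R, rows sqrt(3) R, odd columns
## shifted half a row. The origin carries a quarter-pixel offset so that no
## pixel center falls exactly on a hexagon boundary (membership is then
## unambiguous and independent of tie-breaking).
.hexOriginOffset <- 0.25
hexLatticeCenters <- function(H, W, R) {
  dx <- 1.5 * R
  dy <- sqrt(3) * R
  ic <- seq.int(-1L, ceiling(W / dx) + 1L)
  ir <- seq.int(-1L, ceiling(H / dy) + 1L)
  g <- expand.grid(ir = ir, ic = ic)
  cx <- .hexOriginOffset + R + g$ic * dx
  cy <- .hexOriginOffset + (sqrt(3) / 2) * R + g$ir * dy +
    ifelse(g$ic %% 2L == 1L, dy / 2, 0)
  cbind(row = cy, col = cx)
}

## TRUE for centers whose full hexagon (flat-top, circumradius R) lies inside
## the frame of pixel centers [0, H-1] x [0, W-1]
hexFullyInside <- function(centers, H, W, R) {
  ry <- sqrt(3) / 2 * R
  centers[, "col"] - R >= 0 & centers[, "col"] + R <= W - 1 &
    centers[, "row"] - ry >= 0 & centers[, "row"] + ry <= H - 1
}

#' Tile a frame with hexagonal ROIs
#'
#' Builds a regular flat-top hexagonal tiling with the given across-corners
#' diameter (default 20 um). Pixels are assigned to the nearest hexagon
#' centre, which reproduces the hexagonal partition exactly; only hexagons
#' lying fully inside the frame are kept, and pixels of dropped border
#' hexagons stay unassigned (label 0). Every assigned pixel belongs to
#' exactly one ROI.
#'
#' @param frameShape `c(height, width)` in pixels.
#' @param pixelSizeUm pixel size, micrometres/pixel.
#' @param diameterUm hexagon across-corners diameter, micrometres.
#' @return A [`HexROISet`][HexROISet-class] object.
#' @examples
#' rois <- hexTiling(c(64, 64), pixelSizeUm = 1, diameterUm = 20)
#' nRois(rois)
#' @export
hexTiling <- function(frameShape, pixelSizeUm = 1, diameterUm = 20) {
  H <- as.integer(frameShape[1]); W <- as.integer(frameShape[2])
  dPx <- diameterUm / pixelSizeUm
  if (dPx < 3)
    stop("resolution error: hexagon diameter is ", round(dPx, 2),
         " px; need >= 3 px")
  R <- dPx / 2

  centers <- hexLatticeCenters(H, W, R)
  keep <- hexFullyInside(centers, H, W, R)
  centers <- centers[keep, , drop = FALSE]
  labels <- matrix(0L, H, W)

  if (nrow(centers) > 0) {
    ## order centers row-major for stable ids
    ord <- order(centers[, "row"], centers[, "col"])
    centers <- centers[ord, , drop = FALSE]
    key <- paste(round(centers[, "row"] * 8), round(centers[, "col"] * 8))

    ## exact pixel -> hexagon assignment via axial coordinates + cube rounding
    ## (flat-top lattice with origin at the first lattice center)
    pr <- rep(seq_len(H) - 1, W)
    pc <- rep(seq_len(W) - 1, each = H)
    ox <- pc - R - .hexOriginOffset
    oy <- pr - sqrt(3) / 2 * R - .hexOriginOffset
    qf <- (2 / 3) * ox / R
    rf <- (-ox / 3 + sqrt(3) / 3 * oy) / R
    xr <- round(qf); zr <- round(rf); yr <- round(-qf - rf)
    dx <- abs(xr - qf); dz <- abs(zr - rf); dy <- abs(yr + qf + rf)
    fixX <- dx > dy & dx > dz
    fixZ <- !fixX & dz > dy
    xr[fixX] <- -yr[fixX] - zr[fixX]
    zr[fixZ] <- -xr[fixZ] - yr[fixZ]
    ccol <- .hexOriginOffset + R + 1.5 * R * xr
    crow <- .hexOriginOffset + sqrt(3) / 2 * R + sqrt(3) * R * (zr + xr / 2)
    lab <- match(paste(round(crow * 8), round(ccol * 8)), key)
    hit <- !is.na(lab)
    labels[cbind(pr[hit] + 1L, pc[hit] + 1L)] <- lab[hit]
  }

  new("HexROISet", labels = labels, centers = centers,
      diameterUm = as.numeric(diameterUm), pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Extract per-ROI fluorescence traces from a movie
#'
#' Each trace sample is the mean pixel intensity over the ROI's member pixels
#' in one frame; traces are returned in raw fluorescence units so the
#' baseline/noise model downstream sees the original scale.
#'
#' @param movie a [FluorescenceMovie()].
#' @param rois a [`HexROISet`][HexROISet-class] over the movie's frame shape.
#' @return A list of [CalciumTrace()], one per ROI, in ROI order.
#' @export
extractTraces <- function(movie, rois) {
  stopifnot(is(movie, "FluorescenceMovie"), is(rois, "HexROISet"))
  d <- dim(movie@frames)
  if (!all(dim(rois@labels) == d[1:2]))
    stop("segmentation error: ROI label matrix does not match frame shape")
  n <- nRois(rois)
  if (n == 0L) return(list())
  lab <- as.vector(rois@labels)
  sel <- lab > 0L
  counts <- tabulate(lab[sel], n)
  if (any(counts == 0L))
    stop("segmentation error: ROI with zero pixels")
  mat <- matrix(movie@frames, nrow = d[1] * d[2], ncol = d[3])
  sums <- rowsum(mat[sel, , drop = FALSE], lab[sel], reorder = TRUE)
  means <- sums / counts
  lapply(seq_len(n), function(k)
    CalciumTrace(means[k, ], frameIntervalS = movie@frameIntervalS,
                 units = "raw", roiId = sprintf("roi_%04d", k),
                 metadata = list(centerPx = rois@centers[k, ],
                                 nPixels = counts[k])))
}

#' Estimate baseline fluorescence and Gaussian noise scale
#'
#' The baseline F0 is the median of a running 10th-percentile filter
#' (window `windowS`), which tracks the spike-free floor of the trace. The
#' Gaussian noise scale sigma is fitted to the *negative* deviations from the
#' running 10th-percentile baseline: calcium transients (sparks and slow
#' waves) only push the signal up, so samples below the running low
#' percentile are transient-insensitive, and for Gaussian noise their mean
#' square equals `sigma^2` times a known truncated-normal constant, giving an
#' unbiased scale estimate.
#'
#' @param trace a [CalciumTrace()] with at least 30 samples.
#' @param windowS running-window length in seconds (default 60).
#' @return A [`NoiseEstimate`][NoiseEstimate-class] in the trace's units.
#' @examples
#' tr <- simulateTrace(TraceParams(), seed = 1)
#' estimateNoise(tr)
#' @export
estimateNoise <- function(trace, windowS = 60) {
  stopifnot(is(trace, "CalciumTrace"))
  x <- trace@values
  if (length(x) < 30L)
    stop("input error: trace shorter than 30 samples")
  dt <- trace@frameIntervalS
  w <- oddWindow(windowS, dt, length(x))
  if (length(x) < w)
    stop("input error: trace shorter than the running window")

  B <- runningQuantile(x, w, 0.10)
  neg <- (x - B)[x < B]
  ## E[(z - t)^2 | z < t] for a standard normal truncated below t
  truncConst <- function(t) {
    p <- stats::pnorm(t)
    1 + t * stats::dnorm(t) / p + t^2       # E[z^2|z<t] - 2 t E[z|z<t] + t^2
  }
  pEff <- 0.10
  if (length(neg) == 0L) {
    sigma <- 0
  } else {
    ## first pass assumes the running 10th percentile sits at the noise q10
    sigma <- sqrt(mean(neg^2) / truncConst(stats::qnorm(0.10)))
    ## transients lift the percentile: if a fraction f of samples is
    ## elevated, B is effectively the noise quantile 0.10 / (1 - f);
    ## re-fit with the corrected truncation point (one refinement step)
    f <- mean(x > B + 3 * sigma)
    pEff <- min(0.45, 0.10 / max(1 - f, 0.2))
    sigma <- sqrt(mean(neg^2) / truncConst(stats::qnorm(pEff)))
  }
  ## the running percentile sits at the noise quantile pEff, not 0.10, when
  ## transients occupy part of each window; shift the baseline back so F0 is
  ## the 10th noise percentile regardless of transient occupancy
  f0 <- stats::median(B) +
    (stats::qnorm(0.10) - stats::qnorm(pEff)) * sigma
  new("NoiseEstimate", f0 = f0, sigma = sigma, units = trace@units)
}

#' Convert a raw-fluorescence trace to dF/F
#'
#' `dF/F = (F - F0) / F0` with F0 from [estimateNoise()] (or supplied).
#' Traces already in dF/F units are returned unchanged.
#'
#' @param trace a [CalciumTrace()].
#' @param noise optional [`NoiseEstimate`][NoiseEstimate-class]; estimated
#'   from the trace when missing.
#' @return A [CalciumTrace()] in `"dff"` units.
#' @export
dffTrace <- function(trace, noise = NULL) {
  stopifnot(is(trace, "CalciumTrace"))
  if (trace@units == "dff") return(trace)
  if (is.null(noise)) noise <- estimateNoise(trace)
  if (noise@f0 <= 0) stop("numeric guard error: nonpositive baseline F0")
  CalciumTrace((trace@values - noise@f0) / noise@f0,
               frameIntervalS = trace@frameIntervalS, units = "dff",
               roiId = trace@roiId, metadata = trace@metadata)
}

#' Detect calcium spikes in a trace
#'
#' Implements a "smooth slow dynamic" style threshold detector: the trace is
#' converted to dF/F, a slow baseline (centered running median over
#' `smoothWindowS`) is subtracted, and local maxima of the detrended signal
#' exceeding `kSigma` times the noise scale are marked as spikes. Maxima
#' closer than `refractoryS` are merged, keeping the larger amplitude.
#'
#' @param trace a [CalciumTrace()] (raw or dF/F units).
#' @param noise a [`NoiseEstimate`][NoiseEstimate-class] for the trace;
#'   estimated when missing.
#' @param kSigma detection threshold multiplier (> 0, default 4).
#' @param smoothWindowS slow-baseline window in seconds (default 30).
#' @param refractoryS merge gap in seconds (default 5). The default is wide
#'   enough that, at 1 s sampling, whether two nearby events fuse is decided
#'   by their time separation alone rather than by spark kinetics, so
#'   detected counts depend only on the event-time process.
#' @return A [`SpikeTrain`][SpikeTrain-class].
#' @examples
#' tr <- simulateTrace(TraceParams(sparkRateHz = 0.02), seed = 2)
#' detectSpikes(tr)
#' @export
detectSpikes <- function(trace, noise = NULL, kSigma = 4,
                         smoothWindowS = 30, refractoryS = 5) {
  stopifnot(is(trace, "CalciumTrace"))
  if (kSigma <= 0) stop("'kSigma' must be > 0")
  if (is.null(noise)) noise <- estimateNoise(trace)
  dt <- trace@frameIntervalS

  if (trace@units == "raw") {
    if (noise@f0 <= 0) stop("numeric guard error: nonpositive baseline F0")
    dff <- (trace@values - noise@f0) / noise@f0
    sigma <- noise@sigma / noise@f0
  } else {
    dff <- trace@values
    sigma <- noise@sigma
  }
  if (sigma == 0) {
    if (stats::sd(dff) > 0)
      stop("numeric guard error: sigma = 0 for a non-constant trace")
    return(new("SpikeTrain", times = numeric(0), amplitudes = numeric(0),
               threshold = 0, roiId = trace@roiId))
  }

  w <- oddWindow(smoothWindowS, dt, length(dff))
  d <- dff - runningMedian(dff, w)
  thr <- kSigma * sigma

  n <- length(d)
  isMax <- d > thr
  if (n >= 3) {
    interior <- c(FALSE, d[2:(n - 1)] >= d[1:(n - 2)] &
                         d[2:(n - 1)] > d[3:n], FALSE)
    ## allow peaks at the ends
    interior[1] <- d[1] > d[2]
    interior[n] <- d[n] > d[n - 1]
    isMax <- isMax & interior
  }
  idx <- which(isMax)

  ## merge maxima closer than the refractory gap, keeping the larger
  refr <- max(1L, round(refractoryS / dt))
  if (length(idx) > 1L) {
    repeat {
      gaps <- diff(idx)
      j <- which(gaps < refr)
      if (length(j) == 0L) break
      j <- j[1L]
      drop <- if (d[idx[j]] >= d[idx[j + 1L]]) j + 1L else j
      idx <- idx[-drop]
    }
  }

  new("SpikeTrain", times = (idx - 1) * dt, amplitudes = d[idx],
      threshold = thr, roiId = trace@roiId)
}

#' Keep ROIs whose traces contain spikes
#'
#' @param traces list of [CalciumTrace()].
#' @param detections list of [`SpikeTrain`][SpikeTrain-class], aligned with
#'   `traces` by `roiId`.
#' @param minSpikes minimum spike count to keep an ROI (default 1).
#' @return A list with elements `traces` and `spikes`, order preserved.
#' @export
selectSpikingRois <- function(traces, detections, minSpikes = 1) {
  idT <- vapply(traces, roiId, character(1))
  idD <- vapply(detections, roiId, character(1))
  if (!identical(idT, idD))
    stop("alignment error: trace and detection roi ids differ")
  keep <- vapply(detections, nSpikes, integer(1)) >= minSpikes
  list(traces = traces[keep], spikes = detections[keep])
}
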