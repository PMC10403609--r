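## File-format boundary: grayscale multi-page TIFF movies, JPEG waveform
## images, CSV traces/spikes/manifests. Rasters are lossless in memory; JPEG
## (the required interchange format for waveform images) is used only at the
## I/O boundary.

#' Write a movie as a 16-bit grayscale multi-page TIFF
#'
#' One TIFF page per frame. Intensities are scaled by `scale` (default: fit
#' the movie maximum into 16 bits) and quantized.
#'
#' @param movie a [FluorescenceMovie()].
#' @param path output file path.
#' @param scale intensity multiplier applied before quantization; `NULL`
#'   auto-scales the movie maximum to 65535.
#' @return The path, invisibly.
#' @export
writeMovieTIFF <- function(movie, path, scale = NULL) {
  stopifnot(is(movie, "FluorescenceMovie"))
  arr <- movie@frames
  if (is.null(scale)) {
    mx <- max(arr, 1e-12)
    scale <- 65535 / mx
  }
  pages <- lapply(seq_len(dim(arr)[3]), function(f)
    pmin(pmax(arr[, , f] * scale, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale multi-page TIFF movie
#'
#' @param path TIFF file, 8- or 16-bit grayscale, page = frame.
#' @param pixelSizeUm,frameIntervalS calibration attached to the movie.
#' @return A [FluorescenceMovie()] with intensities in `[0, 1] * 65535`
#'   (16-bit scale).
#' @export
readMovieTIFF <- function(path, pixelSizeUm = 1, frameIntervalS = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  FluorescenceMovie(arr * 65535, pixelSizeUm = pixelSizeUm,
                    frameIntervalS = frameIntervalS)
}

#' Write traces to CSV (one row per sample)
#'
#' Columns `roi_id`, `t_s`, `F`; a JSON sidecar (same path + `.json`) stores
#' units, frame interval and metadata labels.
#'
#' @param traces list of [CalciumTrace()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTracesCSV <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(roi_id = tr@roiId,
               t_s = (seq_along(tr@values) - 1) * tr@frameIntervalS,
               F = tr@values)))
  utils::write.csv(df, path, row.names = FALSE)
  side <- lapply(traces, function(tr)
    list(roi_id = tr@roiId, units = tr@units,
         frame_interval_s = tr@frameIntervalS,
         group = tr@metadata$group, substance = tr@metadata$substance))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read traces written by [writeTracesCSV()]
#'
#' @param path CSV path (the `.json` sidecar is read when present).
#' @return A list of [CalciumTrace()].
#' @export
readTracesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidePath <- paste0(path, ".json")
  side <- if (file.exists(sidePath)) jsonlite::read_json(sidePath) else NULL
  ids <- unique(df$roi_id)
  lapply(ids, function(id) {
    d <- df[df$roi_id == id, ]
    s <- if (!is.null(side))
      Filter(function(x) identical(x$roi_id, id), side)[[1]] else NULL
    dt <- if (!is.null(s)) s$frame_interval_s else
      stats::median(diff(d$t_s))
    CalciumTrace(d$F, frameIntervalS = dt,
                 units = if (!is.null(s)) s$units else "raw", roiId = id,
                 metadata = list(group = s$group, substance = s$substance))
  })
}

#' Write detected spikes to CSV
#'
#' Columns `roi_id`, `t_s`, `amplitude`.
#'
#' @param spikes list of [`SpikeTrain`][SpikeTrain-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeSpikesCSV <- function(spikes, path) {
  rows <- lapply(spikes, function(s)
    if (nSpikes(s) == 0L) NULL else
    data.frame(roi_id = s@roiId, t_s = s@times, amplitude = s@amplitudes))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(roi_id = character(0), t_s = numeric(0),
                     amplitude = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a waveform or composite image as JPEG
#'
#' @param image a [`WaveformImage`][WaveformImage-class],
#'   [`CompositeImage`][CompositeImage-class], or pixel matrix in `[0, 1]`.
#' @param path output JPEG path.
#' @param quality JPEG quality (default 90).
#' @return The path, invisibly.
#' @export
writeImageJPEG <- function(image, path, quality = 90) {
  px <- if (is.matrix(image)) image else imagePixels(image)
  jpeg::writeJPEG(pmin(pmax(px, 0), 1), path, quality = quality / 100)
  invisible(path)
}

#' Write an image-set manifest CSV
#'
#' One row per image: filename, id, group, and (for composites) the nine
#' member ids separated by `;`.
#'
#' @param images list of waveform or composite images.
#' @param filenames character vector of image file names.
#' @param path manifest CSV path.
#' @return The path, invisibly.
#' @export
writeManifestCSV <- function(images, filenames, path) {
  df <- data.frame(
    filename = filenames,
    id = vapply(images, function(x)
      if (is(x, "CompositeImage")) paste(x@memberIds, collapse = ";")
      else x@roiId, character(1)),
    group = vapply(images, imageGroup, character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the hexagonal ROI map (labeled PNG + JSON descriptor)
#'
#' @param rois a [`HexROISet`][HexROISet-class].
#' @param pngPath output PNG (ROI labels as gray levels).
#' @param jsonPath output JSON (centers, diameter, pixel size).
#' @return `pngPath`, invisibly.
#' @export
writeRoiMap <- function(rois, pngPath, jsonPath = paste0(pngPath, ".json")) {
  n <- max(1L, nRois(rois))
  png::writePNG(rois@labels / n, pngPath)
  jsonlite::write_json(
    list(diameter_um = rois@diameterUm, pixel_size_um = rois@pixelSizeUm,
         diameter_convention = "across-corners (circumdiameter), flat-top",
         centers_px = list(row = unname(rois@centers[, "row"]),
                           col = unname(rois@centers[, "col"]))),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(pngPath)
}
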