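## learn_eval: train/evaluate an image classifier on single or composite
## waveform images; voting segregation of unseen substances.
##
## The cloud classifier of the source methodology is replaced by a local,
## seed-deterministic probability random forest (ranger) on block-mean-pooled
## pixel intensities. The backend satisfies the stated contract (separable
## toy sets reach AP ~ 1, label-shuffled data stays at chance) and is
## deliberately lightweight so full benchmarks run on one CPU.

#' Classifier and experiment configuration
#'
#' @param gridPx coarse block-mean-pooled pixel grid (rows, cols) included in
#'   the feature vector.
#' @param rowBandsPerTile number of horizontal bands (per waveform tile) over
#'   which the row-profile statistics are aggregated.
#' @param widthLevelsPerTile number of coarse amplitude levels (per tile) at
#'   which mean stroke widths, and their pairwise differences, are computed.
#' @param numTrees random-forest size.
#' @param renderConfig the [RenderConfig()] used to rasterize traces.
#' @param nComposites composites built per group (`NULL` = pool size).
#' @param equalCount match the number of *distinct waveforms* between the
#'   single and composite arms: the composite arm then builds
#'   `floor(pool / 9)` disjoint composites instead of `nComposites` reused
#'   ones.
#' @param poolFilter `"none"` or `"weakTercile"` (restrict the waveform pool
#'   to the lowest-dynamic-range third before building datasets).
#' @param splitFractions trainval/test fractions.
#' @return A named list of settings.
#' @export
experimentConfig <- function(gridPx = c(16, 32),
                             rowBandsPerTile = 64,
                             widthLevelsPerTile = 12,
                             numTrees = 300,
                             renderConfig = RenderConfig(canvasPx = c(128, 224)),
                             nComposites = NULL,
                             equalCount = FALSE,
                             poolFilter = c("none", "weakTercile"),
                             splitFractions = c(trainval = 0.9, test = 0.1)) {
  poolFilter <- match.arg(poolFilter)
  list(gridPx = as.integer(gridPx),
       rowBandsPerTile = as.integer(rowBandsPerTile),
       widthLevelsPerTile = as.integer(widthLevelsPerTile),
       numTrees = as.integer(numTrees),
       renderConfig = renderConfig,
       nComposites = nComposites,
       equalCount = isTRUE(equalCount),
       poolFilter = poolFilter,
       splitFractions = splitFractions)
}

## Raster feature map. Because the y axis is globally fixed, raster rows
## correspond to fixed dF/F levels, so row-wise statistics are comparable
## across images while being invariant to *where* in time a spark occurred:
##   - a coarse block-mean-pooled pixel grid (gross layout),
##   - per row band: ink fraction, stroke-run count, and mean stroke width
##     (ink / runs) -- the mean width of a spark's stroke at a given height
##     grows linearly with its decay time constant,
##   - pairwise differences of mean widths across coarse amplitude levels,
##     which for exponential decays estimate the decay constant free of the
##     amplitude scale.
## A composite raster is treated as stacked tile bands: `tileRows` fixes the
## per-tile height so bands line up with the same dF/F levels in every tile.
rasterFeatures <- function(M, opts, tileRows) {
  h <- nrow(M); w <- ncol(M)
  nTiles <- max(1L, h %/% tileRows)
  X <- M > 0.5
  grid <- as.vector(meanPool(M, opts$gridPx))

  runsRow <- rowSums(X[, -1L, drop = FALSE] & !X[, -w, drop = FALSE]) +
    X[, 1L]
  inkRow <- rowSums(X)

  nb <- opts$rowBandsPerTile * nTiles
  band <- pmin(floor((seq_len(h) - 1L) * nb / h) + 1L, nb)
  inkB <- as.vector(rowsum(inkRow, band)) / w
  runB <- as.vector(rowsum(runsRow, band))
  widthB <- as.vector(rowsum(inkRow, band)) / pmax(runB, 1)

  nl <- opts$widthLevelsPerTile * nTiles
  lev <- pmin(floor((seq_len(h) - 1L) * nl / h) + 1L, nl)
  widthL <- as.vector(rowsum(inkRow, lev)) / pmax(as.vector(rowsum(runsRow, lev)), 1)
  ## pairwise width differences within each tile band
  diffs <- unlist(lapply(seq_len(nTiles), function(b) {
    wl <- widthL[(b - 1L) * opts$widthLevelsPerTile +
                   seq_len(opts$widthLevelsPerTile)]
    d <- outer(wl, wl, `-`)
    d[upper.tri(d)]
  }))
  c(grid, inkB, runB / w, widthB, diffs)
}

## feature matrix for a list of images (or raw pixel matrices)
imageFeatures <- function(images, opts, tileRows) {
  px <- lapply(images, function(im)
    if (is.matrix(im)) im else imagePixels(im))
  n1 <- length(rasterFeatures(px[[1]], opts, tileRows))
  feat <- t(vapply(px, rasterFeatures, numeric(n1), opts = opts,
                   tileRows = tileRows))
  colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  feat
}

## group labels of a list of images
imageGroups <- function(images) {
  vapply(images, imageGroup, character(1))
}

#' Stratified train-validation / test split
#'
#' Randomly assigns each image to `trainval` or `test`. When stratified (the
#' default) the split is drawn per class with the rounding rule
#' `n_test = round(fractions["test"] * n_class)`, remainder to trainval, so
#' per-class fractions are within one item of target.
#'
#' @param labels character vector of class labels (or a list of images, whose
#'   group labels are used).
#' @param fractions named fractions `c(trainval = 0.9, test = 0.1)`.
#' @param seed split seed.
#' @param stratified stratify by class (default `TRUE`; requires at least 10
#'   images per class).
#' @return A [`SplitAssignment`][SplitAssignment-class].
#' @examples
#' sp <- splitDataset(rep(c("negative", "positive"), each = 50), seed = 1)
#' table(sp@tags)
#' @export
splitDataset <- function(labels, fractions = c(trainval = 0.9, test = 0.1),
                         seed = 1L, stratified = TRUE) {
  if (is.list(labels)) labels <- imageGroups(labels)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(labels)
  tags <- rep("trainval", n)
  if (stratified) {
    tab <- table(labels)
    if (any(tab < 10L))
      stop("stratification error: every class needs >= 10 images; got ",
           paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
    idxTest <- withSeed(seed, {
      unlist(lapply(names(tab), function(cl) {
        idx <- which(labels == cl)
        sample(idx, round(fractions[["test"]] * length(idx)))
      }), use.names = FALSE)
    })
  } else {
    idxTest <- withSeed(seed, sample(n, round(fractions[["test"]] * n)))
  }
  tags[idxTest] <- "test"
  new("SplitAssignment", tags = tags, fractions = as.numeric(fractions),
      seed = as.integer(seed), stratified = isTRUE(stratified))
}

#' Train the waveform-image classifier
#'
#' Computes the deterministic raster features (see [experimentConfig()]) and
#' fits a probability random forest. Training is deterministic given
#' `(images, config, seed)` (single-threaded, seeded forest). Composite
#' images are featurized per tile band: a 3 x 3 composite contributes three
#' stacked band profiles whose rows line up with the same dF/F levels as a
#' single-waveform raster.
#'
#' @param images list of training images (all the same kind/size).
#' @param labels class labels aligned with `images`; exactly two classes must
#'   be present.
#' @param config an [experimentConfig()].
#' @param seed training seed.
#' @return A [`ClassifierModel`][ClassifierModel-class].
#' @export
trainClassifier <- function(images, labels = imageGroups(images),
                            config = experimentConfig(), seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("training error: need 2 classes, got ",
         paste(levels(labels), collapse = ", "))
  if (nlevels(labels) > 2L)
    stop("training error: only binary classification is supported")
  firstPx <- if (is.matrix(images[[1]])) images[[1]] else
    imagePixels(images[[1]])
  tileRows <- if (is(images[[1]], "CompositeImage"))
    nrow(firstPx) %/% 3L else nrow(firstPx)
  opts <- config[c("gridPx", "rowBandsPerTile", "widthLevelsPerTile")]
  feat <- imageFeatures(images, opts, tileRows)
  trainOnFeatures(feat, labels, config, seed, opts, tileRows)
}

## backend fit on a precomputed feature matrix
trainOnFeatures <- function(feat, labels, config, seed, opts, tileRows) {
  labels <- factor(labels)
  df <- as.data.frame(feat)
  df$.class <- labels
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = config$numTrees, probability = TRUE,
    seed = as.integer(seed), num.threads = 1L,
    verbose = FALSE)
  new("ClassifierModel", fit = fit, classes = levels(labels),
      featureOpts = opts, tileRows = as.integer(tileRows),
      seed = as.integer(seed),
      configHash = configHash(c(opts, numTrees = config$numTrees)))
}

## argmax predictions + probabilities from a feature matrix
predictFeatures <- function(model, feat) {
  pr <- stats::predict(model@fit, data = as.data.frame(feat),
                       num.threads = 1L, verbose = FALSE)$predictions
  pr <- pr[, model@classes, drop = FALSE]
  cls <- factor(model@classes[max.col(pr, ties.method = "first")],
                levels = model@classes)
  list(class = cls, prob = pr)
}

#' Predict classes and class probabilities for images
#'
#' @param object a [`ClassifierModel`][ClassifierModel-class].
#' @param images list of images (same kind as at training).
#' @return A list with `class` (factor; argmax with ties going to the first,
#'   i.e. negative, class) and `prob` (matrix of class probabilities).
#' @export
setMethod("predict", "ClassifierModel", function(object, images) {
  predictFeatures(object,
                  imageFeatures(images, object@featureOpts, object@tileRows))
})

## area under the precision-recall curve of the positive-class score
prCurveAuc <- function(scores, truthPositive) {
  ord <- order(scores, decreasing = TRUE)
  rel <- truthPositive[ord]
  nPos <- sum(rel)
  if (nPos == 0L) return(NA_real_)
  prec <- cumsum(rel) / seq_along(rel)
  sum(prec[rel]) / nPos
}

#' Evaluate a classifier on labeled test images
#'
#' Compares argmax predictions to labels: 2 x 2 confusion counts, per-class
#' precision `TP / (TP + FP)` and recall `TP / (TP + FN)`, average precision
#' as the unweighted mean of the two class precisions, plus the area under
#' the positive-class precision-recall curve. A class that is never predicted
#' gets precision 0 and is listed in the report's `degenerate` slot.
#'
#' @param model a [`ClassifierModel`][ClassifierModel-class].
#' @param images non-empty list of test images.
#' @param labels true labels aligned with `images`.
#' @return An [`EvalReport`][EvalReport-class].
#' @export
evaluateModel <- function(model, images, labels = imageGroups(images)) {
  if (length(images) == 0L) stop("input error: empty test set")
  if (!all(labels %in% model@classes))
    stop("label error: unknown label(s) ",
         paste(setdiff(labels, model@classes), collapse = ", "))
  pred <- predict(model, images)
  evaluatePredictions(model, pred, labels)
}

## EvalReport from predictions + truth
evaluatePredictions <- function(model, pred, labels) {
  truth <- factor(labels, levels = model@classes)
  confusion <- table(truth = truth, predicted = pred$class)
  cm <- matrix(as.integer(confusion), 2, 2,
               dimnames = dimnames(confusion))

  precision <- recall <- stats::setNames(numeric(2), model@classes)
  degenerate <- character(0)
  for (cl in model@classes) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    if (tp + fp == 0L) {
      precision[cl] <- 0
      degenerate <- c(degenerate, cl)
    } else precision[cl] <- tp / (tp + fp)
    recall[cl] <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  }
  positive <- model@classes[2L]
  new("EvalReport", confusion = cm, precision = precision, recall = recall,
      averagePrecision = mean(precision),
      prAuc = prCurveAuc(pred$prob[, positive], truth == positive),
      nTest = length(labels), degenerate = degenerate)
}

#' Voting segregation of an untrained substance
#'
#' Predicts every image of a substance the model was never trained on and
#' reports the fraction assigned to the positive class (each image, single or
#' composite, counts once).
#'
#' @param model a [`ClassifierModel`][ClassifierModel-class].
#' @param images non-empty list of images.
#' @param substance substance label for the report.
#' @return A [`SegregationResult`][SegregationResult-class].
#' @export
segregateUnseen <- function(model, images, substance = "unknown") {
  if (length(images) == 0L) stop("input error: empty image set")
  pred <- predict(model, images)
  positive <- model@classes[2L]
  nPos <- sum(pred$class == positive)
  new("SegregationResult", substance = as.character(substance),
      nImages = length(images), nPredictedPositive = as.integer(nPos),
      fractionPositive = nPos / length(images))
}

## restrict a rendered waveform pool (and its trace list) to the lowest
## dynamic-range tercile
weakTercileFilter <- function(dffTraces) {
  dr <- vapply(dffTraces, dynamicRange, numeric(1))
  groups <- vapply(dffTraces, function(x) x@metadata$group, character(1))
  keep <- logical(length(dffTraces))
  for (g in unique(groups)) {
    i <- which(groups == g)
    keep[i[dr[i] <= stats::quantile(dr[i], 1 / 3)]] <- TRUE
  }
  keep
}

#' Run one single-arm or composite-arm benchmark experiment
#'
#' Orchestrates simulate -> dF/F -> render -> split -> (composite) -> train
#' -> evaluate for one benchmark and one arm. The 90/10 split is always
#' drawn at the waveform level; in `"single"` mode the dataset is one image
#' per waveform, while in `"composite"` mode each side's composites are
#' built from its own waveform pool (members may recur across composites
#' within a side, but train and test composites never share a waveform). With `config$equalCount = TRUE` the composite arm
#' instead uses `floor(pool / 9)` disjoint composites so both arms consume
#' the same number of distinct waveforms. With
#' `config$poolFilter = "weakTercile"` only the weakest third of waveforms
#' (lowest dynamic range, per group) enters the pool.
#'
#' @param benchmark a [BenchmarkSpec()].
#' @param mode `"single"` or `"composite"`.
#' @param config an [experimentConfig()].
#' @param seed seed driving simulation, compositing, split and training.
#' @param returnModel return the fitted model and dataset alongside the
#'   report.
#' @return An [`EvalReport`][EvalReport-class], or (with
#'   `returnModel = TRUE`) a list with elements `report`, `model`, `images`,
#'   `labels`, `split`, `traces`.
#' @examples
#' \donttest{
#' rep <- runExperiment(defaultBenchmark(nTracesPerGroup = 60), "single",
#'                      seed = 1)
#' averagePrecision(rep)
#' }
#' @export
runExperiment <- function(benchmark, mode = c("single", "composite"),
                          config = experimentConfig(), seed = 1L,
                          returnModel = FALSE) {
  mode <- match.arg(mode)
  data <- experimentDataset(benchmark, config, seed)
  armExperiment(data, mode, config, seed, returnModel)
}

#' Run both experiment arms on one shared dataset
#'
#' Simulates and renders the benchmark once and runs the single-image and
#' composite-image arms on the same waveform pool, with the same derived
#' seeds as two separate [runExperiment()] calls would use (the reports are
#' identical; the shared pass just avoids simulating twice).
#'
#' @inheritParams runExperiment
#' @return A list with [`EvalReport`][EvalReport-class] elements `single`
#'   and `composite`.
#' @export
compareArms <- function(benchmark, config = experimentConfig(), seed = 1L) {
  data <- experimentDataset(benchmark, config, seed)
  list(single = armExperiment(data, "single", config, seed),
       composite = armExperiment(data, "composite", config, seed))
}

## shared simulate -> dF/F -> (filter) -> render pass
experimentDataset <- function(benchmark, config, seed) {
  validObject(benchmark)
  seeds <- deriveSeeds(seed, 4L)
  spec <- benchmark
  spec@seed <- seeds[1L]
  traces <- makeBenchmark(spec)
  dff <- lapply(traces, dffTrace)
  if (config$poolFilter == "weakTercile")
    dff <- dff[weakTercileFilter(dff)]
  waveforms <- renderWaveforms(dff, config$renderConfig)
  list(traces = traces, waveforms = waveforms,
       wfGroups = imageGroups(waveforms), seeds = seeds)
}

## one arm (train + evaluate) on a prepared dataset
armExperiment <- function(data, mode, config, seed, returnModel = FALSE) {
  waveforms <- data$waveforms
  wfGroups <- data$wfGroups
  traces <- data$traces
  seeds <- data$seeds

  opts <- config[c("gridPx", "rowBandsPerTile", "widthLevelsPerTile")]
  tileRows <- config$renderConfig@canvasPx[1]
  images <- NULL

  ## the trainval/test split is always drawn at the *waveform* level, so in
  ## composite mode train and test composites never share a member waveform
  ## (otherwise the model can recognize memorized waveforms in test
  ## composites and scores above chance even with no group effect)
  split <- splitDataset(wfGroups, config$splitFractions, seed = seeds[3L])
  inTrain <- split@tags == "trainval"

  if (mode == "single") {
    labels <- wfGroups
    feat <- imageFeatures(waveforms, opts, tileRows)
    train <- inTrain
    if (returnModel) images <- waveforms
  } else {
    ## composites are rasterized transiently, one at a time, keeping only
    ## their feature vectors (a full benchmark's composite rasters would not
    ## fit in memory)
    labels <- character(0); train <- logical(0); featList <- list()
    cseeds <- deriveSeeds(seeds[2L], 4L)
    nFeat <- NULL
    k <- 0L
    for (g in sort(unique(wfGroups))) {
      for (side in c(TRUE, FALSE)) {
        k <- k + 1L
        pool <- waveforms[wfGroups == g & inTrain == side]
        if (length(pool) < 9L)
          stop("insufficient-pool error: group '", g, "' has ",
               length(pool), " waveforms in its ",
               if (side) "trainval" else "test", " pool (need >= 9)")
        nOut <- if (config$equalCount) length(pool) %/% 9L
                else if (is.null(config$nComposites)) length(pool)
                else round(config$nComposites *
                             if (side) config$splitFractions[["trainval"]]
                             else config$splitFractions[["test"]])
        plan <- compositePlan(length(pool), nOut, cseeds[k],
                              reuseAcross = !config$equalCount)
        if (is.null(nFeat))
          nFeat <- length(rasterFeatures(
            tile3x3(lapply(pool[rep_len(seq_along(pool), 9)], imagePixels)),
            opts, tileRows))
        gf <- vapply(seq_len(nOut), function(i) {
          raster <- tile3x3(lapply(pool[plan$draws[[i]]], imagePixels),
                            orderSeed = plan$orderSeeds[i])
          rasterFeatures(raster, opts, tileRows)
        }, numeric(nFeat))
        featList[[k]] <- t(gf)
        labels <- c(labels, rep(g, nOut))
        train <- c(train, rep(side, nOut))
      }
    }
    feat <- do.call(rbind, featList)
    colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  }

  if (!returnModel) rm(waveforms)   # release rasters before the forest fit
  model <- trainOnFeatures(feat[train, , drop = FALSE], labels[train],
                           config, seeds[4L], opts, tileRows)
  pred <- predictFeatures(model, feat[!train, , drop = FALSE])
  report <- evaluatePredictions(model, pred, labels[!train])
  if (!returnModel) return(report)
  list(report = report, model = model, images = images, labels = labels,
       split = split, traces = traces)
}
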