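test_that("the 90/10 split is stratified with the stated rounding rule", {
  labels <- rep(c("negative", "positive"), each = 500)
  sp <- splitDataset(labels, seed = 1)
  expect_identical(sum(sp@tags == "test"), 100L)
  expect_identical(sum(sp@tags == "trainval"), 900L)
  # stratified: exactly 50 test per class
  expect_identical(sum(sp@tags == "test" & labels == "negative"), 50L)

  # rounding: 101 images in one class -> 91 / 10
  sp2 <- splitDataset(rep("negative", 101), seed = 2)
  expect_identical(sum(sp2@tags == "test"), 10L)
  expect_identical(sum(sp2@tags == "trainval"), 91L)

  # deterministic
  expect_identical(splitDataset(labels, seed = 9)@tags,
                   splitDataset(labels, seed = 9)@tags)
  expect_false(identical(splitDataset(labels, seed = 9)@tags,
                         splitDataset(labels, seed = 10)@tags))

  # partition property on uneven classes
  lab3 <- c(rep("negative", 83), rep("positive", 67))
  sp3 <- splitDataset(lab3, seed = 3)
  expect_identical(sum(sp3@tags %in% c("trainval", "test")), 150L)
  for (cl in c("negative", "positive")) {
    nT <- sum(sp3@tags == "test" & lab3 == cl)
    expect_lte(abs(nT - 0.1 * sum(lab3 == cl)), 1)
  }

  expect_error(splitDataset(c(rep("a", 5), rep("b", 100))),
               "stratification error")
})

test_that("the classifier satisfies the separability contract", {
  imgs <- toyImageSet(30)
  labels <- imageGroups(imgs)
  sp <- splitDataset(labels, seed = 1)
  model <- trainClassifier(imgs[sp@tags == "trainval"],
                           labels[sp@tags == "trainval"],
                           tinyExperimentConfig(), seed = 1)
  rep <- evaluateModel(model, imgs[sp@tags == "test"],
                       labels[sp@tags == "test"])
  expect_gte(averagePrecision(rep), 0.99)
  expect_equal(unname(classRecall(rep)), c(1, 1))
})

test_that("label-shuffled training stays at chance", {
  # structureless images with seeded random labels
  set.seed(42)
  imgs <- lapply(1:120, function(i) {
    new("WaveformImage", pixels = matrix(runif(32 * 32), 32, 32),
        roiId = paste0("r", i),
        group = sample(c("negative", "positive"), 1),
        metadata = list(), configHash = "x")
  })
  labels <- imageGroups(imgs)
  model <- trainClassifier(imgs[1:60], labels[1:60],
                           tinyExperimentConfig(), seed = 7)
  rep <- evaluateModel(model, imgs[61:120], labels[61:120])
  expect_gte(averagePrecision(rep), 0.4)
  expect_lte(averagePrecision(rep), 0.6)
})

test_that("training and prediction are deterministic given the seed", {
  imgs <- toyImageSet(15)
  labels <- imageGroups(imgs)
  m1 <- trainClassifier(imgs, labels, tinyExperimentConfig(), seed = 3)
  m2 <- trainClassifier(imgs, labels, tinyExperimentConfig(), seed = 3)
  probe <- toyImageSet(5, seed = 9)
  p1 <- predict(m1, probe); p2 <- predict(m2, probe)
  expect_identical(p1$class, p2$class)
  expect_identical(p1$prob, p2$prob)
})

test_that("evaluation reproduces confusion arithmetic exactly", {
  # train a deterministic dark-vs-bright model, then craft a test set whose
  # predictions are known: TP = 9, FP = 1, FN = 2, TN = 8 for "positive"
  imgs <- toyImageSet(15)
  model <- trainClassifier(imgs, imageGroups(imgs), tinyExperimentConfig(),
                           seed = 1)
  test <- c(
    lapply(1:9, function(i) toyImage(0.9, "positive", paste0("tp", i))),
    lapply(1:1, function(i) toyImage(0.9, "negative", paste0("fp", i))),
    lapply(1:2, function(i) toyImage(0.05, "positive", paste0("fn", i))),
    lapply(1:8, function(i) toyImage(0.05, "negative", paste0("tn", i))))
  rep <- evaluateModel(model, test)
  expect_identical(rep@nTest, 20L)
  expect_equal(unname(classPrecision(rep)["positive"]), 0.9)
  expect_equal(unname(classRecall(rep)["positive"]), 9 / 11,
               tolerance = 1e-12)
  # brute-force confusion from raw predictions
  pred <- predict(model, test)$class
  truth <- factor(imageGroups(test), levels = model@classes)
  expect_identical(confusionMatrix(rep),
                   matrix(as.integer(table(truth, pred)), 2, 2,
                          dimnames = dimnames(confusionMatrix(rep))))
  # counts sum to the test size
  expect_identical(sum(confusionMatrix(rep)), 20L)

  expect_error(evaluateModel(model, test, rep("weird", 20)), "label error")
})

test_that("a never-predicted class is reported degenerate with precision 0", {
  imgs <- toyImageSet(15)
  model <- trainClassifier(imgs, imageGroups(imgs), tinyExperimentConfig(),
                           seed = 1)
  # all-bright test set: everything is predicted positive
  test <- lapply(1:10, function(i)
    toyImage(0.9, if (i <= 5) "positive" else "negative", paste0("t", i)))
  rep <- evaluateModel(model, test)
  expect_identical(rep@degenerate, "negative")
  expect_identical(unname(classPrecision(rep)["negative"]), 0)
})

test_that("voting segregation reports the positive fraction", {
  imgs <- toyImageSet(15)
  model <- trainClassifier(imgs, imageGroups(imgs), tinyExperimentConfig(),
                           seed = 1)
  # 74 bright + 26 dark unlabeled images -> 74% voted positive
  unseen <- c(lapply(1:74, function(i) toyImage(0.9, "unknown", paste0("u", i))),
              lapply(1:26, function(i) toyImage(0.05, "unknown", paste0("v", i))))
  seg <- segregateUnseen(model, unseen, substance = "haloperidol-like")
  expect_identical(seg@nImages, 100L)
  expect_identical(seg@nPredictedPositive, 74L)
  expect_equal(fractionPositive(seg), 0.74)
  expect_error(segregateUnseen(model, list()), "input error")
})

test_that("an unseen positive-kinetics substance votes mostly positive", {
  # train on the default benchmark, challenge traces simulated with the
  # positive group's kinetics under a fresh seed (an "untrained substance")
  res <- suppressWarnings(
    runExperiment(tinyBenchmark(n = 60, seed = 2), "single",
                  tinyExperimentConfig(), seed = 2, returnModel = TRUE))
  ch <- makeBenchmark(BenchmarkSpec(nTracesPerGroup = 40, seed = 77,
    negativeParams = TraceParams(effectKnob = 0),
    positiveParams = TraceParams(effectKnob = 0.6)))
  chPos <- ch[vapply(ch, function(x) x@metadata$group, character(1)) ==
              "positive"]
  imgs <- suppressWarnings(
    renderWaveforms(lapply(chPos, dffTrace),
                    RenderConfig(canvasPx = c(64, 96))))
  seg <- segregateUnseen(res$model, imgs, "haloperidol-like")
  expect_gt(fractionPositive(seg), 0.5)
})

test_that("equal-waveform-count control shrinks the composite advantage", {
  cfg <- tinyExperimentConfig()
  cfgEq <- tinyExperimentConfig(equalCount = TRUE)
  gapFull <- gapEq <- numeric(2)
  for (i in 1:2) {
    b <- defaultBenchmark(nTracesPerGroup = 200, seed = 10 + i)
    full <- suppressWarnings(compareArms(b, cfg, seed = 10 + i))
    eq <- suppressWarnings(runExperiment(b, "composite", cfgEq, seed = 10 + i))
    gapFull[i] <- averagePrecision(full$composite) -
      averagePrecision(full$single)
    gapEq[i] <- averagePrecision(eq) - averagePrecision(full$single)
  }
  # matching the number of distinct waveforms removes most of the advantage
  expect_lt(mean(gapEq), mean(gapFull) + 0.05)
})

test_that("weak-signal pools do not disadvantage the composite arm", {
  cfg <- tinyExperimentConfig()
  cfgWeak <- tinyExperimentConfig(poolFilter = "weakTercile")
  dC <- dS <- numeric(2)
  for (i in 1:2) {
    b <- defaultBenchmark(nTracesPerGroup = 300, seed = 20 + i)
    full <- suppressWarnings(compareArms(b, cfg, seed = 20 + i))
    weak <- suppressWarnings(compareArms(b, cfgWeak, seed = 20 + i))
    # drop in AP caused by restricting to the weakest dynamic-range third
    dC[i] <- averagePrecision(full$composite) -
      averagePrecision(weak$composite)
    dS[i] <- averagePrecision(full$single) - averagePrecision(weak$single)
  }
  expect_lte(mean(dC), mean(dS) + 0.1)
})
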