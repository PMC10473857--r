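test_that("the VGG variant manifest has the documented 24 layers", {
  m <- buildModel("vgg19_variant", widths = c(2, 2, 2, 2, 2), seed = 1)
  mf <- layerManifest(m)
  expect_identical(nrow(mf), 24L)
  kinds <- table(mf$kind)
  expect_identical(as.integer(kinds[["conv"]]), 5L)
  expect_identical(as.integer(kinds[["batch_norm"]]), 5L)
  expect_identical(as.integer(kinds[["activation"]]), 5L)
  expect_identical(as.integer(kinds[["pool"]]), 5L)
  expect_identical(as.integer(kinds[["fully_connected"]]), 1L)
})

test_that("the ResNet-50 manifest has 49 conv layers plus 1 FC", {
  m <- buildModel("resnet50", widthScale = 0.125, seed = 1)
  mf <- layerManifest(m)
  expect_identical(sum(mf$kind == "conv"), 49L)
  expect_identical(sum(mf$kind == "fully_connected"), 1L)
  expect_identical(sum(mf$kind == "shortcut_conv"), 4L)
  expect_identical(sum(mf$kind == "residual_add"), 16L)
})

test_that("analytic gradients match central differences on a tiny net", {
  ns <- asNamespace("grainsight")
  ns$.reset_layer_ids()
  layers <- list(ns$.conv_lyr(2L, 3L, 3L, 1L, 1L),
                 ns$.bn_lyr(3L),
                 ns$.relu_lyr(),
                 ns$.maxpool_lyr(2L, 2L),
                 ns$.flatten_lyr(),
                 ns$.fc_lyr(3L * 3L * 3L, 2L))
  set.seed(7)
  pb <- ns$.init_layer_params(layers, list(), list())
  X <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  y <- c(1L, 2L, 1L)
  lossAt <- function(params) {
    fw <- ns$.nn_forward(layers, params, pb$buffers, X, training = TRUE)
    ns$.ce_loss(ns$.softmax(fw$out), y)
  }
  fw <- ns$.nn_forward(layers, pb$params, pb$buffers, X, training = TRUE)
  grads <- ns$.nn_backward(layers, pb$params, fw$caches,
                           ns$.ce_grad(ns$.softmax(fw$out), y))$grads
  eps <- 1e-5
  set.seed(8)
  for (nm in names(grads)) {
    v <- pb$params[[nm]]
    for (j in sample(length(v), min(4, length(v)))) {
      p1 <- pb$params; p1[[nm]][j] <- v[j] + eps
      p2 <- pb$params; p2[[nm]][j] <- v[j] - eps
      num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][j]),
                1e-4 * max(1, abs(num)))
    }
  }
})

test_that("training rejects degenerate inputs", {
  m <- buildModel("vgg19_variant", widths = c(2, 2, 2, 2, 2), seed = 1)
  crops <- generateCropSet(4, seed = 5)
  bad <- crops
  bad@info$label <- rep("perfect", 4)
  expect_error(trainClassifier(m, bad), "single class")
  expect_error(trainClassifier(m, crops, labels = rep("weird", 4)),
               "class levels")
})

test_that("a tiny model trains and predicts with sane probabilities", {
  m <- buildModel("vgg19_variant", widths = c(2, 2, 2, 2, 2), seed = 3)
  crops <- generateCropSet(12, seed = 4)
  tm <- trainClassifier(m, crops,
                        config = trainConfig(maxEpochs = 2, batchSize = 6,
                                             validationFraction = 0,
                                             seed = 3))
  expect_gt(length(tm@history), 0L)
  pred <- predictGrains(tm, crops)
  expect_identical(nrow(pred), 12L)
  expect_true(all(pred$label %in% c("perfect", "imperfect")))
  expect_equal(pred$prob_perfect + pred$prob_imperfect, rep(1, 12))
  empty <- predictGrains(tm, crops@tensor[, , , 0, drop = FALSE])
  expect_identical(nrow(empty), 0L)
})

test_that("evaluation and model comparison behave as documented", {
  r <- evaluateClassification(
    c("perfect", "perfect", "imperfect", "imperfect"),
    c("perfect", "imperfect", "imperfect", "imperfect"))
  expect_equal(overallAccuracy(r), 0.75)
  expect_identical(sum(confusionMatrix(r)), 4L)
  expect_equal(unname(perClassAccuracy(r)["imperfect"]), 2 / 3)
  r2 <- evaluateClassification(c("perfect"), c("perfect"))
  expect_identical(compareModels(list(a = r, b = r2)), "b")
  expect_identical(
    compareModels(list(a = r2, b = r2), modelSizes = c(a = 9, b = 2)),
    "b")
  expect_error(evaluateClassification("perfect", character(0)),
               "lengths differ")
})

test_that("save/load round-trips a classifier and its manifest", {
  m <- buildModel("vgg19_variant", widths = c(2, 2, 2, 2, 2), seed = 6)
  f <- tempfile(fileext = ".rds")
  saveClassifier(m, f)
  m2 <- loadClassifier(f)
  expect_identical(m2@params, m@params)
  expect_identical(layerManifest(m2), layerManifest(m))
  mf <- jsonlite::read_json(sub("\\.rds$", "_manifest.json", f),
                            simplifyVector = TRUE)
  expect_identical(nrow(mf), 24L)
  unlink(c(f, sub("\\.rds$", "_manifest.json", f)))
})
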