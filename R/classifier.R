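#' @include nn-engine.R
NULL

# width progressions; the published layer taxonomy fixes the layer
# counts, the widths are free design parameters
.VGG_WIDTHS <- c(32L, 64L, 128L, 256L, 512L)
.RESNET_DEPTHS <- c(3L, 4L, 6L, 3L)

.layers_vgg <- function(inC, nClasses, widths) {
  .reset_layer_ids()
  layers <- list()
  prevC <- inC
  side <- 100L
  for (s in seq_along(widths)) {
    layers <- c(layers, list(
      .conv_lyr(prevC, widths[s], 3L, 1L, 1L),
      .bn_lyr(widths[s]),
      .relu_lyr(),
      .maxpool_lyr(2L, 2L)))
    prevC <- widths[s]
    side <- side %/% 2L
  }
  c(layers, list(.flatten_lyr(),
                 .fc_lyr(side * side * prevC, nClasses)))
}

.bottleneck <- function(inC, midC, outC, stride, project) {
  branch <- list(
    .conv_lyr(inC, midC, 1L, stride, 0L), .bn_lyr(midC), .relu_lyr(),
    .conv_lyr(midC, midC, 3L, 1L, 1L), .bn_lyr(midC), .relu_lyr(),
    .conv_lyr(midC, outC, 1L, 1L, 0L), .bn_lyr(outC))
  shortcut <- if (project)
    list(.conv_lyr(inC, outC, 1L, stride, 0L, role = "shortcut_conv"),
         .bn_lyr(outC))
  .res_lyr(branch, shortcut)
}

.layers_resnet50 <- function(inC, nClasses, widthScale) {
  .reset_layer_ids()
  w <- function(x) max(1L, as.integer(round(x * widthScale)))
  layers <- list(
    .conv_lyr(inC, w(64), 7L, 2L, 3L), .bn_lyr(w(64)), .relu_lyr(),
    .maxpool_lyr(3L, 2L, 1L))
  stageIn <- w(64)
  mids <- c(64, 128, 256, 512)
  for (s in 1:4) {
    midC <- w(mids[s]); outC <- w(mids[s] * 4)
    stride <- if (s == 1L) 1L else 2L
    for (bk in seq_len(.RESNET_DEPTHS[s])) {
      layers <- c(layers, list(.bottleneck(
        stageIn, midC, outC, if (bk == 1L) stride else 1L, bk == 1L)))
      stageIn <- outC
    }
  }
  c(layers, list(.gap_lyr(), .fc_lyr(stageIn, nClasses)))
}

# flatten the layer structure into the published taxonomy; projection
# 1x1 shortcut convolutions are tagged separately and not counted
# among the convolutional layers, following the 49 = 1 + 3 x
# (3 + 4 + 6 + 3) accounting convention for ResNet-50
.layer_manifest <- function(layers) {
  rows <- list(data.frame(kind = "input", detail = ""))
  expand <- function(lys) {
    for (ly in lys) {
      if (ly$kind %in% c("conv", "shortcut_conv")) {
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = ly$kind,
          detail = sprintf("%dx%d, %d->%d, stride %d",
                           ly$k, ly$k, ly$inC, ly$outC, ly$stride))
      } else if (ly$kind == "batch_norm") {
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = "batch_norm", detail = sprintf("%d channels", ly$C))
      } else if (ly$kind == "activation") {
        rows[[length(rows) + 1L]] <<- data.frame(kind = "activation",
                                                 detail = "relu")
      } else if (ly$kind == "pool") {
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = "pool",
          detail = if (ly$pool == "max")
            sprintf("max %dx%d stride %d", ly$k, ly$k, ly$stride)
          else "global average")
      } else if (ly$kind == "fully_connected") {
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = "fully_connected",
          detail = sprintf("%d -> %d", ly$inD, ly$outD))
      } else if (ly$kind == "residual_block") {
        expand(ly$branch)
        if (!is.null(ly$shortcut)) expand(ly$shortcut)
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = "residual_add",
          detail = paste0(ly$variant, " shortcut + relu"))
      }
    }
  }
  expand(layers)
  rows[[length(rows) + 1L]] <- data.frame(kind = "softmax", detail = "")
  rows[[length(rows) + 1L]] <- data.frame(kind = "output", detail = "")
  do.call(rbind, rows)
}

#' Build a grain-quality CNN
#'
#' Two architectures are available. \code{"vgg19_variant"} is a
#' compact VGG-style network of five stages, each a 3x3 convolution,
#' batch normalization, ReLU and 2x2 max pooling, followed by one
#' fully-connected layer and softmax; under the taxonomy input /
#' 5 conv / 5 batch-norm / 5 activation / 5 pool / fully-connected /
#' softmax / output it totals 24 layers. \code{"resnet50"} is the
#' 50-layer residual network: a 7x7 stem convolution, four stages of
#' bottleneck blocks with depths (3, 4, 6, 3) (each block three
#' convolutions, Y = F(X) + x; the first block of a stage uses a
#' projection shortcut), global average pooling and one
#' fully-connected layer: 49 convolutional layers plus 1
#' fully-connected.
#'
#' Both accept five-channel 100 x 100 crops by default; channel widths
#' are configurable so a desk-scale (CPU-trainable) variant keeps the
#' exact layer structure at reduced width.
#'
#' @param architecture \code{"vgg19_variant"} or \code{"resnet50"}.
#' @param inputChannels crop channels (5 for RGB+NIR+NIR; 3 for an
#'   RGB-only ablation).
#' @param nClasses number of classes (2: perfect/imperfect).
#' @param widths five stage widths for the VGG variant.
#' @param widthScale width multiplier for ResNet-50.
#' @param seed RNG seed for weight initialization.
#' @return an untrained \linkS4class{GrainClassifier}
#' @examples
#' m <- buildModel("vgg19_variant", widths = c(4, 8, 16, 32, 64))
#' nrow(layerManifest(m))  # 24
#' @export
buildModel <- function(architecture = c("vgg19_variant", "resnet50"),
                       inputChannels = 5L, nClasses = 2L,
                       widths = .VGG_WIDTHS, widthScale = 1,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  set.seed(seed)
  layers <- if (architecture == "vgg19_variant") {
    stopifnot(length(widths) == 5L)
    .layers_vgg(as.integer(inputChannels), as.integer(nClasses),
                as.integer(widths))
  } else {
    .layers_resnet50(as.integer(inputChannels), as.integer(nClasses),
                     widthScale)
  }
  ini <- .init_layer_params(layers, list(), list())
  new("GrainClassifier", architecture = architecture, layers = layers,
      params = ini$params, buffers = ini$buffers,
      inputShape = c(100L, 100L, as.integer(inputChannels)),
      nClasses = as.integer(nClasses),
      classLevels = c("perfect", "imperfect"), trained = FALSE,
      history = data.frame())
}

#' Training configuration
#'
#' Defaults follow the reference protocol: a cap of 100 epochs and
#' learning rate 0.001 (Adam), with early stopping on a validation
#' split (patience 10). Desk-scale runs typically pass a smaller
#' \code{maxEpochs}.
#'
#' @param maxEpochs epoch cap (>= 1).
#' @param learningRate Adam step size (> 0).
#' @param batchSize minibatch size.
#' @param seed RNG seed controlling shuffling (and the whole run).
#' @param optimizer only \code{"adam"} is implemented.
#' @param earlyStopPatience epochs without validation improvement
#'   before stopping; ignored when \code{validationFraction} is 0.
#' @param validationFraction fraction of the training crops held out
#'   for early stopping.
#' @return a config list
#' @export
trainConfig <- function(maxEpochs = 100L, learningRate = 0.001,
                        batchSize = 32L, seed = 1L, optimizer = "adam",
                        earlyStopPatience = 10L,
                        validationFraction = 0.1) {
  stopifnot(maxEpochs >= 1L, learningRate > 0, batchSize >= 1L,
            identical(optimizer, "adam"),
            validationFraction >= 0, validationFraction < 1)
  list(maxEpochs = as.integer(maxEpochs), learningRate = learningRate,
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       optimizer = optimizer,
       earlyStopPatience = as.integer(earlyStopPatience),
       validationFraction = validationFraction)
}

.crops_to_x <- function(crops, inC) {
  x <- if (is(crops, "GrainCropSet")) crops@tensor else crops
  stopifnot(length(dim(x)) == 4L)
  if (dim(x)[3] > inC) x <- x[, , seq_len(inC), , drop = FALSE]
  if (dim(x)[3] != inC)
    stop("crops have ", dim(x)[3], " channels; model expects ", inC,
         call. = FALSE)
  x / 255
}

#' Train a grain classifier
#'
#' Minimizes the two-class cross-entropy with Adam on minibatches.
#' All stochastic sources (shuffling, validation split) are seeded, so
#' the run is deterministic given the config seed. The history records
#' per-epoch training loss and accuracy (and validation accuracy when
#' a validation split is used); with a validation split, the
#' best-validation parameters are restored at the end.
#'
#' @param model an untrained (or trained) \linkS4class{GrainClassifier}.
#' @param crops a \linkS4class{GrainCropSet} (labels in
#'   \code{cropInfo}) or a 4-D array with \code{labels} supplied.
#' @param labels optional character/factor labels overriding the crop
#'   info.
#' @param config see \code{\link{trainConfig}}.
#' @param verbose print per-epoch progress.
#' @return the trained \linkS4class{GrainClassifier}
#' @export
trainClassifier <- function(model, crops, labels = NULL,
                            config = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "GrainClassifier"))
  if (is.null(labels)) {
    if (!is(crops, "GrainCropSet") || !"label" %in% names(crops@info))
      stop("labels are required", call. = FALSE)
    labels <- crops@info$label
  }
  labels <- as.character(labels)
  if (!all(labels %in% model@classLevels))
    stop("labels outside the model's class levels", call. = FALSE)
  x <- .crops_to_x(crops, model@inputShape[3])
  n <- dim(x)[4]
  stopifnot(length(labels) == n)
  yIdx <- match(labels, model@classLevels)
  if (length(unique(yIdx)) < 2L)
    stop("training set contains a single class", call. = FALSE)

  set.seed(config$seed)
  nVal <- floor(config$validationFraction * n)
  valIdx <- if (nVal > 0L) sample(n, nVal) else integer(0)
  trIdx <- setdiff(seq_len(n), valIdx)
  if (length(unique(yIdx[trIdx])) < 2L)
    stop("training split contains a single class", call. = FALSE)

  params <- model@params; buffers <- model@buffers
  adam <- .adam_init(params[.collect_params(model@layers)])
  hist <- list()
  bestVal <- -Inf; bestParams <- params; bestBuffers <- buffers
  sinceBest <- 0L

  evalAcc <- function(idx, params, buffers) {
    if (length(idx) == 0L) return(NA_real_)
    preds <- integer(length(idx))
    bs <- max(config$batchSize, 32L)
    for (s in split(seq_along(idx), ceiling(seq_along(idx) / bs))) {
      fw <- .nn_forward(model@layers, params, buffers,
                        x[, , , idx[s], drop = FALSE], training = FALSE)
      preds[s] <- max.col(t(fw$out))
    }
    mean(preds == yIdx[idx])
  }

  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample(trIdx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epLoss <- 0; epHits <- 0L
    for (b in batches) {
      xb <- x[, , , b, drop = FALSE]
      fw <- .nn_forward(model@layers, params, buffers, xb,
                        training = TRUE)
      buffers <- fw$buffers
      probs <- .softmax(fw$out)
      loss <- .ce_loss(probs, yIdx[b])
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      epLoss <- epLoss + loss * length(b)
      epHits <- epHits + sum(max.col(t(probs)) == yIdx[b])
      bw <- .nn_backward(model@layers, params, fw$caches,
                         .ce_grad(probs, yIdx[b]))
      up <- .adam_step(params[names(bw$grads)], bw$grads, adam,
                       config$learningRate)
      params[names(bw$grads)] <- up$params
      adam <- up$state
    }
    trLoss <- epLoss / length(ord)
    trAcc <- epHits / length(ord)
    valAcc <- evalAcc(valIdx, params, buffers)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = trLoss,
                                accuracy = trAcc, valAccuracy = valAcc)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f val %.3f",
                      epoch, trLoss, trAcc, valAcc))
    if (length(valIdx) > 0L) {
      if (valAcc > bestVal + 1e-12) {
        bestVal <- valAcc; bestParams <- params
        bestBuffers <- buffers; sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$earlyStopPatience) break
      }
    }
  }
  if (length(valIdx) > 0L) {
    params <- bestParams; buffers <- bestBuffers
  }
  model@params <- params
  model@buffers <- buffers
  model@trained <- TRUE
  model@history <- do.call(rbind, hist)
  model
}

#' Classify grain crops
#'
#' Softmax class probabilities and argmax labels; stateless, so
#' predictions do not depend on the crop order.
#'
#' @param model a \linkS4class{GrainClassifier}.
#' @param crops a \linkS4class{GrainCropSet} or 4-D array.
#' @param batchSize forward-pass batch size.
#' @return data.frame with \code{label} and one probability column per
#'   class; zero rows for an empty crop set
#' @export
predictGrains <- function(model, crops, batchSize = 64L) {
  stopifnot(is(model, "GrainClassifier"))
  x <- .crops_to_x(crops, model@inputShape[3])
  n <- dim(x)[4]
  pcols <- paste0("prob_", model@classLevels)
  if (n == 0L) {
    out <- data.frame(label = character(0))
    for (pc in pcols) out[[pc]] <- numeric(0)
    return(out)
  }
  if (!identical(as.integer(dim(x)[1:2]), model@inputShape[1:2]))
    stop("crop size ", dim(x)[1], "x", dim(x)[2],
         " does not match model input ", model@inputShape[1], "x",
         model@inputShape[2], call. = FALSE)
  probs <- matrix(0, model@nClasses, n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    fw <- .nn_forward(model@layers, model@params, model@buffers,
                      x[, , , s, drop = FALSE], training = FALSE)
    probs[, s] <- .softmax(fw$out)
  }
  out <- data.frame(label = model@classLevels[max.col(t(probs))])
  for (k in seq_len(model@nClasses)) out[[pcols[k]]] <- probs[k, ]
  out
}

#' Evaluate predictions against true labels
#'
#' @param predicted,truth equal-length label vectors over
#'   (perfect, imperfect).
#' @param levels class ordering for the confusion matrix.
#' @return an \linkS4class{EvaluationReport} (rows = truth, columns =
#'   predicted; overall accuracy = trace / total)
#' @examples
#' r <- evaluateClassification(c("perfect", "imperfect"),
#'                             c("perfect", "imperfect"))
#' overallAccuracy(r)  # 1
#' @export
evaluateClassification <- function(predicted, truth,
                                   levels = c("perfect", "imperfect")) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ", call. = FALSE)
  cm <- table(factor(truth, levels), factor(predicted, levels))
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(truth = levels, predicted = levels))
  tot <- sum(cm)
  pca <- diag(cm) / pmax(rowSums(cm), 1L)
  names(pca) <- levels
  new("EvaluationReport", confusionMatrix = cm, perClassAccuracy = pca,
      overallAccuracy = if (tot > 0) sum(diag(cm)) / tot else NaN)
}

#' Choose between candidate models
#'
#' Selects the report with the highest overall accuracy; exact ties go
#' to the smaller model (fewest parameters) when sizes are given,
#' otherwise to the first.
#'
#' @param reports a named list of \linkS4class{EvaluationReport}s (a
#'   single report is returned as the choice).
#' @param modelSizes optional named numeric parameter counts.
#' @return name of the chosen entry
#' @export
compareModels <- function(reports, modelSizes = NULL) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  if (is.null(names(reports)))
    names(reports) <- paste0("model", seq_along(reports))
  acc <- vapply(reports, overallAccuracy, numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1L && !is.null(modelSizes))
    best <- best[order(modelSizes[names(acc)[best]])]
  names(acc)[best[1L]]
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is R's native serialization; alongside it an
#' architecture-manifest JSON is written for inspection.
#'
#' @param model a \linkS4class{GrainClassifier}.
#' @param path checkpoint path (\code{.rds}).
#' @return \code{saveClassifier}: the path, invisibly;
#'   \code{loadClassifier}: the model
#' @export
saveClassifier <- function(model, path) {
  stopifnot(is(model, "GrainClassifier"))
  saveRDS(model, path)
  jsonlite::write_json(layerManifest(model),
                       sub("\\.rds$", "_manifest.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "GrainClassifier"))
  m
}
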