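#' @include AllGenerics.R
NULL

#' Construct a five-channel image
#'
#' @param planes an (H, W, 5) numeric array, or \code{NULL} if the five
#'   planes are given individually.
#' @param r,g,b,nir1,nir2 individual H x W planes (used when
#'   \code{planes} is \code{NULL}).
#' @return a \linkS4class{MultiChannelImage}
#' @examples
#' img <- multiChannelImage(array(128, dim = c(8, 8, 5)))
#' channelNames(img)
#' @export
multiChannelImage <- function(planes = NULL, r, g, b, nir1, nir2) {
  if (is.null(planes)) {
    pl <- list(R = r, G = g, B = b, NIR1 = nir1, NIR2 = nir2)
    d <- dim(pl[[1]])
    for (nm in names(pl))
      if (!identical(dim(pl[[nm]]), d))
        stop("plane '", nm, "' has mismatched dimensions", call. = FALSE)
    planes <- array(unlist(pl, use.names = FALSE), dim = c(d, 5L))
  }
  dimnames(planes) <- list(NULL, NULL, .CHANNELS)
  new("MultiChannelImage", planes = planes)
}

#' @rdname MultiChannelImage-class
#' @export
setMethod("channelNames", "MultiChannelImage", function(x) .CHANNELS)

#' @rdname MultiChannelImage-class
#' @export
setMethod("getPlane", "MultiChannelImage", function(x, channel) {
  if (is.character(channel)) channel <- match(channel, .CHANNELS)
  if (is.na(channel) || channel < 1L || channel > 5L)
    stop("unknown channel", call. = FALSE)
  x@planes[, , channel]
})

#' @rdname MultiChannelImage-class
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@planes))

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@planes)
  cat("MultiChannelImage:", d[1], "x", d[2], "pixels,",
      paste(.CHANNELS, collapse = "+"), "\n")
})

## ---- SceneGroundTruth / GrainScene accessors ----

#' @rdname SceneGroundTruth-class
#' @export
setMethod("instanceMask", "SceneGroundTruth", function(x) x@instanceMask)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("grainLabels", "SceneGroundTruth", function(x) x@labels)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("defectTypes", "SceneGroundTruth", function(x) x@defectTypes)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("clusterIds", "SceneGroundTruth", function(x) x@clusterIds)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("grainParams", "SceneGroundTruth", function(x) x@grainParams)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("nGrains", "SceneGroundTruth", function(x) length(x@labels))

#' @rdname SceneGroundTruth-class
#' @export
setMethod("instanceMask", "GrainScene", function(x) x@truth@instanceMask)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("grainLabels", "GrainScene", function(x) x@truth@labels)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("defectTypes", "GrainScene", function(x) x@truth@defectTypes)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("clusterIds", "GrainScene", function(x) x@truth@clusterIds)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("grainParams", "GrainScene", function(x) x@truth@grainParams)
#' @rdname SceneGroundTruth-class
#' @export
setMethod("nGrains", "GrainScene", function(x) length(x@truth@labels))

setMethod("show", "GrainScene", function(object) {
  cat("GrainScene:", object@spec@width, "x", object@spec@height,
      "px,", nGrains(object), "grains (",
      sum(object@truth@labels == "imperfect"), "imperfect ),",
      "seed", object@spec@seed, "\n")
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@width, "x", object@height, "px,",
      object@nGrains, "grains, adhesionProb", object@adhesionProb,
      ", imperfectFrac", object@imperfectFrac, ", seed", object@seed, "\n")
})

## ---- regions ----

#' @rdname RegionSet-class
#' @export
setMethod("labelMatrix", "RegionSet", function(x) x@labelMatrix)
#' @rdname RegionSet-class
#' @export
setMethod("regionStats", "RegionSet", function(x) x@stats)
#' @rdname RegionSet-class
#' @export
setMethod("length", "RegionSet", function(x) nrow(x@stats))

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet:", nrow(object@stats), "regions (",
      object@connectivity, "-connected )\n", sep = "")
})

#' @rdname TriageResult-class
#' @export
setMethod("singles", "TriageResult", function(x)
  x@regions@stats[x@triageClass == "single", , drop = FALSE])
#' @rdname TriageResult-class
#' @export
setMethod("adhered", "TriageResult", function(x)
  x@regions@stats[x@triageClass == "adhered", , drop = FALSE])

setMethod("show", "TriageResult", function(object) {
  cat("TriageResult:", sum(object@triageClass == "single"), "single /",
      sum(object@triageClass == "adhered"), "adhered",
      "( roundness <", object@thresholdUsed,
      "or area >", round(object@areaGateUsed, 1), ")\n")
})

#' @rdname SplitResult-class
#' @export
setMethod("labelMatrix", "SplitResult", function(x) x@labelMatrix)

setMethod("show", "SplitResult", function(object) {
  cat("SplitResult:", object@nSegments, "segments,",
      sum(object@labelMatrix == -1L), "watershed-line pixels\n")
})

#' @rdname GrainMasks-class
#' @param x a \linkS4class{GrainMasks}
#' @export
setMethod("labelMatrix", "GrainMasks", function(x) x@labelMatrix)
#' @rdname GrainMasks-class
#' @export
setMethod("length", "GrainMasks", function(x) nrow(x@provenance))

setMethod("show", "GrainMasks", function(object) {
  cat("GrainMasks:", nrow(object@provenance), "grain masks (",
      sum(object@provenance$fromAdhered), "from split clumps )\n")
})

## ---- crops ----

#' @rdname GrainCropSet-class
#' @export
setMethod("cropTensor", "GrainCropSet", function(x) x@tensor)
#' @rdname GrainCropSet-class
#' @export
setMethod("cropInfo", "GrainCropSet", function(x) x@info)
#' @rdname GrainCropSet-class
#' @export
setMethod("length", "GrainCropSet", function(x) dim(x@tensor)[4])

setMethod("show", "GrainCropSet", function(object) {
  d <- dim(object@tensor)
  cat("GrainCropSet:", d[4], "crops of", d[1], "x", d[2], "x", d[3], "\n")
})

## ---- classifier / evaluation ----

#' @rdname GrainClassifier-class
#' @export
setMethod("layerManifest", "GrainClassifier", function(x)
  .layer_manifest(x@layers))

#' @rdname GrainClassifier-class
#' @export
setMethod("trainingHistory", "GrainClassifier", function(x) x@history)

setMethod("show", "GrainClassifier", function(object) {
  mf <- layerManifest(object)
  np <- sum(vapply(object@params, length, numeric(1)))
  cat("GrainClassifier <", object@architecture, ">: input ",
      paste(object@inputShape, collapse = "x"), ", ",
      sum(mf$kind == "conv"), " conv layers, ",
      format(np, big.mark = ","), " parameters, ",
      if (object@trained) "trained" else "untrained", "\n", sep = "")
})

#' @rdname EvaluationReport-class
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(x)
  x@confusionMatrix)
#' @rdname EvaluationReport-class
#' @export
setMethod("overallAccuracy", "EvaluationReport", function(x)
  x@overallAccuracy)
#' @rdname EvaluationReport-class
#' @export
setMethod("perClassAccuracy", "EvaluationReport", function(x)
  x@perClassAccuracy)

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport: overall accuracy",
      sprintf("%.1f%%", 100 * object@overallAccuracy), "\n")
  print(object@confusionMatrix)
})
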