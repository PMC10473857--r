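#' @include grainsight-package.R
NULL

.CHANNELS <- c("R", "G", "B", "NIR1", "NIR2")

#' Five-channel multispectral image
#'
#' An H x W x 5 raster holding the co-registered R, G, B and two
#' near-infrared planes produced by a prism-split five-channel camera
#' (or by the synthetic scene generator). Intensities are 8-bit,
#' stored as numerics in [0, 255].
#'
#' @slot planes numeric array of dimension (H, W, 5), plane order
#'   R, G, B, NIR1, NIR2.
#' @exportClass MultiChannelImage
setClass("MultiChannelImage", representation(planes = "array"))

setValidity("MultiChannelImage", function(object) {
  d <- dim(object@planes)
  if (length(d) != 3L || d[3] != 5L)
    return("planes must be an (H, W, 5) array")
  if (anyNA(object@planes))
    return("planes must not contain NA")
  rng <- range(object@planes)
  if (rng[1] < 0 || rng[2] > 255)
    return("intensities must lie in [0, 255]")
  TRUE
})

#' Scene specification for the synthetic grain-scene generator
#'
#' Describes a backlit multispectral scene of rice grains: geometry of
#' the grain population, adhesion (touching-grain) behaviour, defect
#' phenotype mix, and background contamination. All lengths are pixels.
#'
#' @slot width,height scene dimensions in pixels.
#' @slot nGrains number of grains to place.
#' @slot adhesionProb probability that a grain is placed touching an
#'   already-placed grain, forming an adhesion cluster.
#' @slot imperfectFrac probability that a grain is imperfect.
#' @slot defectMix named probabilities over the imperfect phenotypes
#'   \code{lesion}, \code{mildew}, \code{immature}; must sum to 1.
#' @slot grainLengthPx mean and sd of the grain major-axis length.
#' @slot aspectRatio mean and sd of the major/minor axis ratio.
#' @slot noiseRate expected salt-noise specks per 1e4 background pixels.
#' @slot impurityCount number of small non-grain debris blobs.
#' @slot seed integer RNG seed; the whole scene is deterministic given it.
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  width = "integer", height = "integer", nGrains = "integer",
  adhesionProb = "numeric", imperfectFrac = "numeric",
  defectMix = "numeric", grainLengthPx = "numeric",
  aspectRatio = "numeric", noiseRate = "numeric",
  impurityCount = "integer", seed = "integer"))

setValidity("SceneSpec", function(object) {
  p <- c(object@adhesionProb, object@imperfectFrac)
  if (object@nGrains < 0L) return("nGrains must be >= 0")
  if (object@width < 1L || object@height < 1L)
    return("scene dimensions must be positive")
  if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0, 1]")
  if (length(object@defectMix) != 3L ||
      !identical(names(object@defectMix), c("lesion", "mildew", "immature")))
    return("defectMix must be named (lesion, mildew, immature)")
  if (any(object@defectMix < 0) || abs(sum(object@defectMix) - 1) > 1e-9)
    return("defectMix must be nonnegative and sum to 1")
  if (object@grainLengthPx[1] <= 0) return("grain length mean must be > 0")
  if (object@aspectRatio[1] <= 1) return("aspect ratio mean must be > 1")
  if (object@noiseRate < 0) return("noiseRate must be >= 0")
  if (object@impurityCount < 0L) return("impurityCount must be >= 0")
  TRUE
})

#' Exact per-grain ground truth for a generated scene
#'
#' @slot instanceMask integer H x W raster; 0 = background, k = grain k.
#' @slot labels character vector, per-grain class
#'   (\code{"perfect"}/\code{"imperfect"}).
#' @slot defectTypes character vector; defect phenotype for imperfect
#'   grains (\code{"lesion"}, \code{"mildew"}, \code{"immature"}),
#'   \code{NA} for perfect grains.
#' @slot clusterIds integer vector; grains sharing a value form one
#'   adhesion cluster.
#' @slot grainParams data.frame of per-grain ellipse parameters
#'   (centerRow, centerCol, semiMajor, semiMinor, theta).
#' @exportClass SceneGroundTruth
setClass("SceneGroundTruth", representation(
  instanceMask = "matrix", labels = "character",
  defectTypes = "character", clusterIds = "integer",
  grainParams = "data.frame"))

setValidity("SceneGroundTruth", function(object) {
  n <- length(object@labels)
  ids <- sort(unique(object@instanceMask[object@instanceMask > 0L]))
  if (n > 0L && !identical(as.integer(ids), seq_len(n)))
    return("instanceMask must contain exactly the grain ids 1..n")
  if (length(object@defectTypes) != n || length(object@clusterIds) != n)
    return("per-grain vectors must have one entry per grain")
  if (!all(object@labels %in% c("perfect", "imperfect")))
    return("labels must be 'perfect' or 'imperfect'")
  TRUE
})

#' A generated scene: image, pre-noise rendering, and ground truth
#'
#' @slot image the noisy \linkS4class{MultiChannelImage} as "acquired".
#' @slot noiseless the same rendering before additive noise and salt
#'   specks (after optics smoothing); used by photometric checks.
#' @slot truth the \linkS4class{SceneGroundTruth}.
#' @slot spec the generating \linkS4class{SceneSpec}.
#' @exportClass GrainScene
setClass("GrainScene", representation(
  image = "MultiChannelImage", noiseless = "MultiChannelImage",
  truth = "SceneGroundTruth", spec = "SceneSpec"))

#' Labeled connected foreground regions with shape descriptors
#'
#' @slot labelMatrix integer raster of dense region labels (0 background).
#' @slot stats data.frame with one row per region: label, area,
#'   perimeter, roundness, centroidRow, centroidCol, bbox (half-open,
#'   0-based rows bboxRow0/bboxCol0/bboxRow1/bboxCol1).
#' @slot connectivity 4 or 8.
#' @exportClass RegionSet
setClass("RegionSet", representation(
  labelMatrix = "matrix", stats = "data.frame", connectivity = "integer"))

#' Triage of regions into single grains and adhered clumps
#'
#' @slot regions the underlying \linkS4class{RegionSet}.
#' @slot triageClass character per region: \code{"single"} or
#'   \code{"adhered"}.
#' @slot thresholdUsed roundness cut-off applied.
#' @slot areaGateUsed area gate in pixels (regions larger are adhered);
#'   \code{Inf} when no gate could be derived.
#' @slot widthGateUsed minor-axis gate in pixels (wider regions are
#'   adhered); \code{Inf} when no gate could be derived.
#' @exportClass TriageResult
setClass("TriageResult", representation(
  regions = "RegionSet", triageClass = "character",
  thresholdUsed = "numeric", areaGateUsed = "numeric",
  widthGateUsed = "numeric"))

#' Watershed split of one adhered region
#'
#' @slot labelMatrix integer raster over the full scene: 0 outside the
#'   parent region, -1 watershed-line pixels, k >= 1 basin (segment) k.
#' @slot nSegments number of basins found.
#' @exportClass SplitResult
setClass("SplitResult", representation(
  labelMatrix = "matrix", nSegments = "integer"))

#' Final per-grain masks of a scene
#'
#' @slot labelMatrix integer raster, 0 background, k = grain mask k
#'   (watershed-line pixels belong to no grain).
#' @slot provenance data.frame per mask: maskId, parentRegion,
#'   fromAdhered (logical), splitFailed (logical; an adhered region
#'   that produced a single basin and was passed through).
#' @exportClass GrainMasks
setClass("GrainMasks", representation(
  labelMatrix = "matrix", provenance = "data.frame"))

#' A set of fixed-size five-channel per-grain crops
#'
#' @slot tensor numeric array (size, size, 5, n) of 8-bit intensities.
#' @slot info data.frame per crop: scene, regionLabel, and optionally
#'   label (\code{"perfect"}/\code{"imperfect"}) and defectType.
#' @exportClass GrainCropSet
setClass("GrainCropSet", representation(tensor = "array", info = "data.frame"))

setValidity("GrainCropSet", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 4L || d[3] != 5L)
    return("tensor must be (size, size, 5, n)")
  if (d[1] != d[2]) return("crops must be square")
  if (nrow(object@info) != d[4])
    return("info must have one row per crop")
  TRUE
})

#' Convolutional grain-quality classifier
#'
#' Holds a compact VGG-style or ResNet-50-style network built by
#' \code{\link{buildModel}} together with its parameters, training
#' configuration and history. The network runs on the package's native
#' convolution engine; no external deep-learning framework is used.
#'
#' @slot architecture \code{"vgg19_variant"} or \code{"resnet50"}.
#' @slot layers list of layer descriptors (structure only).
#' @slot params named list of weight arrays.
#' @slot buffers named list of batch-norm running statistics.
#' @slot inputShape integer (H, W, C).
#' @slot nClasses number of output classes.
#' @slot classLevels class names in output order.
#' @slot trained logical.
#' @slot history data.frame of per-epoch loss/accuracy (empty until
#'   trained).
#' @exportClass GrainClassifier
setClass("GrainClassifier", representation(
  architecture = "character", layers = "list", params = "list",
  buffers = "list", inputShape = "integer", nClasses = "integer",
  classLevels = "character", trained = "logical",
  history = "data.frame"))

#' Classification evaluation report
#'
#' @slot confusionMatrix 2 x 2 counts, rows = truth, columns = predicted.
#' @slot perClassAccuracy named accuracies per true class.
#' @slot overallAccuracy trace / total.
#' @exportClass EvaluationReport
setClass("EvaluationReport", representation(
  confusionMatrix = "matrix", perClassAccuracy = "numeric",
  overallAccuracy = "numeric"))

setValidity("EvaluationReport", function(object) {
  cm <- object@confusionMatrix
  if (!all(dim(cm) == c(2L, 2L))) return("confusion matrix must be 2 x 2")
  tot <- sum(cm)
  if (tot > 0 && abs(object@overallAccuracy - sum(diag(cm)) / tot) > 1e-12)
    return("overallAccuracy must equal trace/sum")
  TRUE
})
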