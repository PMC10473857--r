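#' @include AllClasses.R
NULL

#' @rdname MultiChannelImage-class
#' @param object,x a \linkS4class{MultiChannelImage}
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname MultiChannelImage-class
#' @param channel channel index (1..5) or name
#' @export
setGeneric("getPlane", function(x, channel) standardGeneric("getPlane"))

#' @rdname SceneGroundTruth-class
#' @param x a \linkS4class{SceneGroundTruth} or \linkS4class{GrainScene}
#' @export
setGeneric("instanceMask", function(x) standardGeneric("instanceMask"))

#' @rdname SceneGroundTruth-class
#' @export
setGeneric("grainLabels", function(x) standardGeneric("grainLabels"))

#' @rdname SceneGroundTruth-class
#' @export
setGeneric("defectTypes", function(x) standardGeneric("defectTypes"))

#' @rdname SceneGroundTruth-class
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname SceneGroundTruth-class
#' @export
setGeneric("grainParams", function(x) standardGeneric("grainParams"))

#' @rdname SceneGroundTruth-class
#' @export
setGeneric("nGrains", function(x) standardGeneric("nGrains"))

#' @rdname RegionSet-class
#' @param x a \linkS4class{RegionSet}, \linkS4class{GrainMasks} or
#'   \linkS4class{SplitResult}
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname RegionSet-class
#' @export
setGeneric("regionStats", function(x) standardGeneric("regionStats"))

#' @rdname TriageResult-class
#' @param x a \linkS4class{TriageResult}
#' @export
setGeneric("singles", function(x) standardGeneric("singles"))

#' @rdname TriageResult-class
#' @export
setGeneric("adhered", function(x) standardGeneric("adhered"))

#' @rdname GrainCropSet-class
#' @param x a \linkS4class{GrainCropSet}
#' @export
setGeneric("cropTensor", function(x) standardGeneric("cropTensor"))

#' @rdname GrainCropSet-class
#' @export
setGeneric("cropInfo", function(x) standardGeneric("cropInfo"))

#' @rdname GrainClassifier-class
#' @param x a \linkS4class{GrainClassifier}
#' @export
setGeneric("layerManifest", function(x) standardGeneric("layerManifest"))

#' @rdname GrainClassifier-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname EvaluationReport-class
#' @param x an \linkS4class{EvaluationReport}
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("perClassAccuracy", function(x) standardGeneric("perClassAccuracy"))
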