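#' @include classifier.R stacking.R
NULL

#' Match detected grain masks to ground-truth instances
#'
#' Each detected mask is assigned the ground-truth grain covering the
#' largest share of its pixels (majority overlap); masks whose best
#' overlap is below \code{minOverlap} of their area stay unmatched.
#'
#' @param masks a \linkS4class{GrainMasks}.
#' @param truth a \linkS4class{SceneGroundTruth} (or
#'   \linkS4class{GrainScene}).
#' @param minOverlap minimum overlap fraction for a match.
#' @return data.frame per mask: maskId, matchedGrain (NA if
#'   unmatched), overlapFrac, trueLabel
#' @export
matchToGroundTruth <- function(masks, truth, minOverlap = 0.5) {
  if (is(truth, "GrainScene")) truth <- truth@truth
  inst <- truth@instanceMask
  labm <- labelMatrix(masks)
  stopifnot(identical(dim(inst), dim(labm)))
  ids <- masks@provenance$maskId
  matched <- rep(NA_integer_, length(ids))
  ofrac <- numeric(length(ids))
  both <- labm > 0L & inst > 0L
  tab <- table(labm[both], inst[both])
  areas <- tabulate(labm[labm > 0L], nbins = max(ids, 0L))
  for (k in seq_along(ids)) {
    row <- rownames(tab) == as.character(ids[k])
    if (!any(row) || areas[ids[k]] == 0L) next
    counts <- tab[row, ]
    j <- which.max(counts)
    ofrac[k] <- counts[j] / areas[ids[k]]
    if (ofrac[k] >= minOverlap)
      matched[k] <- as.integer(colnames(tab)[j])
  }
  data.frame(maskId = ids, matchedGrain = matched, overlapFrac = ofrac,
             trueLabel = ifelse(is.na(matched), NA_character_,
                                truth@labels[matched]))
}

#' Run the full inspection pipeline on one scene
#'
#' Preprocess (gray, denoise, Otsu, small-component removal), label and
#' triage regions by roundness, split adhered clumps by clamped-gradient
#' watershed, crop every grain mask to a five-channel 100 x 100 stack,
#' and -- when a trained classifier is supplied -- classify each grain.
#' Deterministic: the same scene and model give the same table.
#'
#' @param scene a \linkS4class{GrainScene} (or a
#'   \linkS4class{MultiChannelImage}).
#' @param model optional trained \linkS4class{GrainClassifier}.
#' @param minArea small-component threshold; defaults from the scene
#'   spec when available.
#' @param roundnessThreshold triage cut-off.
#' @param outDir optional directory; when given, the phenotype table
#'   (CSV), a summary JSON and a run manifest JSON are written there.
#' @return list with \code{phenotypes} (data.frame: grain_id,
#'   centroid_row, centroid_col, area, perimeter, roundness,
#'   major_axis, minor_axis, from_adhered, and predicted_class /
#'   class_probability when a model is given), \code{masks}
#'   (\linkS4class{GrainMasks}), \code{crops}
#'   (\linkS4class{GrainCropSet}) and \code{summary} (list)
#' @export
runInspection <- function(scene, model = NULL, minArea = NULL,
                          roundnessThreshold = 0.5, outDir = NULL) {
  image <- if (is(scene, "GrainScene")) scene@image else scene
  stopifnot(is(image, "MultiChannelImage"))
  if (is.null(minArea)) {
    minArea <- if (is(scene, "GrainScene"))
      defaultMinArea(scene@spec) else 12L
  }
  seg <- segmentScene(image, minArea = minArea,
                      roundnessThreshold = roundnessThreshold)
  masks <- seg$masks
  prov <- masks@provenance
  labm <- labelMatrix(masks)
  n <- nrow(prov)

  # per-final-mask shape statistics (recomputed on the final masks so
  # split fragments get their own descriptors)
  phen <- if (n > 0L) {
    # final masks may touch after splitting; measure each mask alone
    stats <- do.call(rbind, lapply(seq_len(n), function(k) {
      one <- labelRegions(labm == prov$maskId[k])
      one@stats[1, c("area", "perimeter", "roundness", "centroidRow",
                     "centroidCol", "majorAxis", "minorAxis")]
    }))
    data.frame(grain_id = prov$maskId,
               centroid_row = stats$centroidRow,
               centroid_col = stats$centroidCol,
               area = stats$area, perimeter = stats$perimeter,
               roundness = stats$roundness,
               major_axis = stats$majorAxis,
               minor_axis = stats$minorAxis,
               from_adhered = prov$fromAdhered)
  } else {
    data.frame(grain_id = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), area = integer(0),
               perimeter = numeric(0), roundness = numeric(0),
               major_axis = numeric(0), minor_axis = numeric(0),
               from_adhered = logical(0))
  }

  crops <- extractCrops(image, masks,
                        size = if (is.null(model)) 100L
                        else model@inputShape[1])
  if (!is.null(model)) {
    stopifnot(is(model, "GrainClassifier"))
    pred <- predictGrains(model, crops)
    phen$predicted_class <- pred$label
    phen$class_probability <- apply(
      as.matrix(pred[, paste0("prob_", model@classLevels)]), 1, max)
  }

  summary <- list(
    n_grains_detected = n,
    n_from_adhered = sum(prov$fromAdhered),
    n_split_failed = sum(prov$splitFailed),
    otsu_threshold = seg$threshold,
    mean_roundness = if (n > 0L) mean(phen$roundness) else NA)
  if (!is.null(model)) {
    summary$n_perfect <- sum(phen$predicted_class == "perfect")
    summary$n_imperfect <- sum(phen$predicted_class == "imperfect")
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(phen, file.path(outDir, "phenotypes.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      files = c("phenotypes.csv", "summary.json"),
      image_size = as.integer(dim(image@planes)[1:2]),
      min_area = as.integer(minArea),
      roundness_threshold = roundnessThreshold,
      classifier = if (is.null(model)) NULL else model@architecture)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(phenotypes = phen, masks = masks, crops = crops,
       summary = summary)
}

#' Benchmark grain counting on synthetic scenes
#'
#' Generates \code{nScenes} scenes (seeds \code{spec@seed, spec@seed +
#' 1, ...}), runs segmentation, and compares the detected grain count
#' with the exact ground truth. Per-scene counting accuracy is
#' \code{1 - |detected - true| / true}.
#'
#' @param spec a \linkS4class{SceneSpec} template.
#' @param nScenes number of scenes.
#' @param verbose print per-scene counts.
#' @return list with \code{perScene} (data.frame: seed, trueCount,
#'   detectedCount, accuracy), \code{meanAccuracy} and
#'   \code{meanAbsErrorPct}
#' @export
benchmarkCounting <- function(spec, nScenes = 10L, verbose = FALSE) {
  stopifnot(is(spec, "SceneSpec"), nScenes >= 1L)
  rows <- vector("list", nScenes)
  for (i in seq_len(nScenes)) {
    sp <- spec
    sp@seed <- spec@seed + i - 1L
    sc <- generateScene(sp)
    res <- runInspection(sc)
    trueN <- nGrains(sc)
    detN <- res$summary$n_grains_detected
    rows[[i]] <- data.frame(seed = sp@seed, trueCount = trueN,
                            detectedCount = detN,
                            accuracy = 1 - abs(detN - trueN) / trueN)
    if (verbose)
      message(sprintf("seed %d: true %d detected %d", sp@seed, trueN,
                      detN))
  }
  perScene <- do.call(rbind, rows)
  list(perScene = perScene, meanAccuracy = mean(perScene$accuracy),
       meanAbsErrorPct = 100 * mean(abs(perScene$detectedCount -
                                          perScene$trueCount) /
                                      perScene$trueCount))
}
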