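#' @include watershed.R
NULL

#' Stack RGB and two NIR planes into a five-channel image
#'
#' Assembles the fixed plane order (R, G, B, NIR1, NIR2); every output
#' plane is bit-identical to its source.
#'
#' @param rgb an (H, W, 3) array, or an H x W matrix for \code{r} with
#'   \code{g}, \code{b} supplied separately.
#' @param nir1,nir2 H x W matrices.
#' @param g,b green and blue planes when \code{rgb} is a single plane.
#' @return a \linkS4class{MultiChannelImage}
#' @export
stackFive <- function(rgb, nir1, nir2, g = NULL, b = NULL) {
  if (is.matrix(rgb) && !is.null(g)) {
    r <- rgb
  } else {
    if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
      stop("rgb must be an (H, W, 3) array", call. = FALSE)
    r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  }
  d <- dim(r)
  for (nm in c("g", "b", "nir1", "nir2")) {
    p <- get(nm)
    if (!identical(dim(p), d))
      stop("plane '", toupper(nm), "' has mismatched dimensions ",
           paste(dim(p), collapse = "x"), " vs ",
           paste(d, collapse = "x"), call. = FALSE)
  }
  multiChannelImage(r = r, g = g, b = b, nir1 = nir1, nir2 = nir2)
}

# bilinear resize by interpolation matrices; exact identity when the
# size is unchanged (pixel-center coordinate mapping)
.resize_bilinear <- function(m, outH, outW) {
  mk <- function(nIn, nOut) {
    src <- ((seq_len(nOut) - 0.5) * nIn / nOut) - 0.5
    src <- pmin(pmax(src, 0), nIn - 1)
    lo <- floor(src); w <- src - lo
    A <- matrix(0, nOut, nIn)
    A[cbind(seq_len(nOut), lo + 1)] <- 1 - w
    hi <- pmin(lo + 2, nIn)
    A[cbind(seq_len(nOut), hi)] <- A[cbind(seq_len(nOut), hi)] + w
    A
  }
  mk(nrow(m), outH) %*% m %*% t(mk(ncol(m), outW))
}

#' Extract a fixed-size five-channel crop for one grain
#'
#' Takes the grain mask's bounding box, masks the surroundings
#' according to \code{backgroundFill}, pads symmetrically to a square,
#' and resizes with bilinear interpolation to \code{size} x
#' \code{size}; the identical geometric transform is applied to all
#' five planes and the result is rounded half-up to 8-bit.
#'
#' \code{backgroundFill = "zero"} (default) zeroes every pixel outside
#' the grain mask, so the classifier sees the grain only;
#' \code{"scene_background"} keeps the raw scene window (edge-clamped
#' where the square extends past the image).
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param grainMask logical matrix with exactly one connected
#'   component.
#' @param size output side length in pixels (the classifier input is
#'   100).
#' @param backgroundFill \code{"zero"} or \code{"scene_background"}.
#' @return a (size, size, 5) numeric array
#' @export
cropGrain <- function(image, grainMask, size = 100L,
                      backgroundFill = c("zero", "scene_background")) {
  backgroundFill <- match.arg(backgroundFill)
  stopifnot(is(image, "MultiChannelImage"), is.logical(grainMask),
            identical(dim(grainMask), dim(image@planes)[1:2]))
  if (!any(grainMask)) stop("empty grain mask", call. = FALSE)
  H <- nrow(grainMask); W <- ncol(grainMask)
  pix <- which(grainMask, arr.ind = TRUE)
  r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
  c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
  h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
  side <- max(h, w)
  # symmetric square window around the bbox
  padTop <- (side - h) %/% 2L
  padLeft <- (side - w) %/% 2L
  rows <- (r0 - padTop):(r0 - padTop + side - 1L)
  cols <- (c0 - padLeft):(c0 - padLeft + side - 1L)
  rowsCl <- pmin(pmax(rows, 1L), H)
  colsCl <- pmin(pmax(cols, 1L), W)
  inWin <- rows >= 1L & rows <= H
  inWinC <- cols >= 1L & cols <= W
  out <- array(0, dim = c(size, size, 5L))
  maskWin <- matrix(FALSE, side, side)
  maskWin[inWin, inWinC] <-
    grainMask[rowsCl[inWin], colsCl[inWinC], drop = FALSE]
  for (ch in 1:5) {
    win <- image@planes[rowsCl, colsCl, ch, drop = TRUE]
    if (backgroundFill == "zero") win[!maskWin] <- 0
    res <- .resize_bilinear(win, size, size)
    out[, , ch] <- pmin(pmax(floor(res + 0.5), 0), 255)
  }
  dimnames(out) <- list(NULL, NULL, .CHANNELS)
  out
}

#' Extract crops for all grain masks of a scene
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param masks a \linkS4class{GrainMasks} (or a
#'   \linkS4class{RegionSet}).
#' @param size,backgroundFill see \code{\link{cropGrain}}.
#' @param scene scene identifier stored with each crop.
#' @param labels optional per-mask class labels.
#' @return a \linkS4class{GrainCropSet}; crop count equals mask count
#' @export
extractCrops <- function(image, masks, size = 100L,
                         backgroundFill = "zero", scene = "scene",
                         labels = NULL) {
  labm <- labelMatrix(masks)
  ids <- if (is(masks, "GrainMasks")) masks@provenance$maskId
  else masks@stats$label
  n <- length(ids)
  tensor <- array(0, dim = c(size, size, 5L, n))
  for (k in seq_len(n))
    tensor[, , , k] <- cropGrain(image, labm == ids[k], size,
                                 backgroundFill)
  info <- data.frame(scene = rep(scene, n), regionLabel = ids)
  info$label <- if (is.null(labels)) NA_character_ else labels
  new("GrainCropSet", tensor = tensor, info = info)
}

#' Generate a labeled crop set for classifier training
#'
#' Renders single-grain scenes with the synthetic generator (per-crop
#' seeds \code{seed, seed + 1, ...}) and extracts the ground-truth
#' grain as a five-channel crop. With \code{balance = TRUE} the class
#' sequence alternates perfect/imperfect so the set is exactly
#' balanced; otherwise each grain is imperfect with probability
#' \code{imperfectFrac}.
#'
#' @param n number of crops.
#' @param imperfectFrac imperfect probability when not balanced.
#' @param balance force an exactly balanced set.
#' @param defectMix,grainLengthPx,aspectRatio,noiseRate see
#'   \code{\link{sceneSpec}}.
#' @param size,backgroundFill see \code{\link{cropGrain}}.
#' @param seed base RNG seed.
#' @return a \linkS4class{GrainCropSet} with \code{label} and
#'   \code{defectType} filled in
#' @export
generateCropSet <- function(n, imperfectFrac = 0.5, balance = TRUE,
                            defectMix = c(lesion = 0.4, mildew = 0.3,
                                          immature = 0.3),
                            grainLengthPx = c(30, 1.2),
                            aspectRatio = c(3, 0.18), noiseRate = 2,
                            size = 100L, backgroundFill = "zero",
                            seed = 1L) {
  tensor <- array(0, dim = c(size, size, 5L, n))
  lab <- character(n); dtype <- character(n)
  for (i in seq_len(n)) {
    frac <- if (balance) as.numeric(i %% 2L == 0L) else imperfectFrac
    sp <- sceneSpec(width = 72, height = 72, nGrains = 1L,
                    adhesionProb = 0, imperfectFrac = frac,
                    defectMix = defectMix, grainLengthPx = grainLengthPx,
                    aspectRatio = aspectRatio, noiseRate = noiseRate,
                    impurityCount = 0L, seed = seed + i - 1L)
    sc <- generateScene(sp)
    tensor[, , , i] <- cropGrain(sc@image, instanceMask(sc) == 1L, size,
                                 backgroundFill)
    lab[i] <- grainLabels(sc)[1]
    dtype[i] <- defectTypes(sc)[1]
  }
  info <- data.frame(scene = sprintf("crop%05d", seq_len(n)),
                     regionLabel = 1L, label = lab, defectType = dtype)
  new("GrainCropSet", tensor = tensor, info = info)
}

#' Write crops as multi-page TIFF files plus a CSV index
#'
#' One 5-page TIFF per crop (one page per channel, 8-bit) and an
#' index CSV (file, scene, regionLabel, label).
#'
#' @param crops a \linkS4class{GrainCropSet}.
#' @param outDir output directory.
#' @return path of the index CSV, invisibly
#' @export
writeCrops <- function(crops, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  info <- crops@info
  files <- character(nrow(info))
  for (k in seq_len(nrow(info))) {
    f <- file.path(outDir, sprintf("crop%05d.tiff", k))
    pages <- lapply(1:5, function(ch) crops@tensor[, , ch, k] / 255)
    tiff::writeTIFF(pages, f, bits.per.sample = 8L)
    files[k] <- basename(f)
  }
  idx <- cbind(file = files, info)
  csv <- file.path(outDir, "crops.csv")
  write.csv(idx, csv, row.names = FALSE)
  invisible(csv)
}
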