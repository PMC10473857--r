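#' @include synthetic-scenes.R
NULL

#' Weighted grayscale conversion of a five-channel image
#'
#' Pixelwise weighted sum of the five planes, rounded half-up to 8-bit.
#' The default weights are the Rec.601 luminance coefficients on the
#' RGB planes with the NIR planes excluded: binarization is driven by
#' the color image, while the NIR planes feed classification.
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param channelWeights five nonnegative coefficients summing to 1,
#'   ordered (R, G, B, NIR1, NIR2).
#' @return an integer grayscale matrix in [0, 255]
#' @examples
#' img <- multiChannelImage(array(rep(c(60, 120, 180, 0, 0),
#'                          each = 16), dim = c(4, 4, 5)))
#' toGray(img, c(1, 1, 1, 0, 0) / 3)[1, 1]  # 120
#' @export
toGray <- function(image,
                   channelWeights = c(0.299, 0.587, 0.114, 0, 0)) {
  stopifnot(is(image, "MultiChannelImage"))
  if (length(channelWeights) != 5L || any(channelWeights < 0) ||
      abs(sum(channelWeights) - 1) > 1e-9)
    stop("channelWeights must be 5 nonnegative values summing to 1",
         call. = FALSE)
  d <- dim(image@planes)
  g <- matrix(0, d[1], d[2])
  for (k in 1:5)
    if (channelWeights[k] > 0)
      g <- g + channelWeights[k] * image@planes[, , k]
  matrix(as.integer(floor(g + 0.5)), d[1], d[2])
}

#' Gaussian denoising
#'
#' Convolution with a truncated, normalized Gaussian kernel (truncation
#' radius \code{ceiling(3 * sigma)}), borders handled by reflection.
#' \code{sigma = 0} returns the input unchanged.
#'
#' @param gray a numeric matrix (grayscale image).
#' @param sigma Gaussian standard deviation in pixels, >= 0.
#' @return a numeric matrix of the same dimensions
#' @export
gaussianDenoise <- function(gray, sigma = 1.0) {
  if (!is.matrix(gray)) stop("gray must be a matrix", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  .gblur(gray * 1.0, sigma)
}

#' Otsu threshold of an intensity sample
#'
#' Exhaustive maximization of the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over the 256-bin
#' histogram. The returned threshold t assigns bins <= t to class 0.
#' Ties in the variance are broken toward the smallest t.
#'
#' @param x numeric vector or matrix of intensities in [0, 255]
#'   (binned by \code{floor} into 256 bins).
#' @return the threshold, an integer in 0..254
#' @export
otsuThreshold <- function(x) {
  v <- floor(pmin(pmax(as.numeric(x), 0), 255))
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct ",
         "intensities", call. = FALSE)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[256]
  w1 <- 1 - w0
  num <- (muT * w0 - mu)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, -Inf)
  bcv <- bcv[1:255]                       # t = 255 leaves class 1 empty
  which.max(bcv) - 1L                     # first maximum = smallest t
}

#' Otsu binarization
#'
#' Thresholds a grayscale image at the Otsu threshold. With
#' \code{polarity = "dark_foreground"} (the backlit-stage default)
#' pixels <= t become foreground; with \code{"bright_foreground"}
#' pixels > t do.
#'
#' @param gray numeric matrix with at least two distinct intensities.
#' @param polarity \code{"dark_foreground"} or \code{"bright_foreground"}.
#' @return list with \code{mask} (logical matrix) and
#'   \code{threshold}
#' @export
binarizeOtsu <- function(gray,
                         polarity = c("dark_foreground",
                                      "bright_foreground")) {
  polarity <- match.arg(polarity)
  t <- otsuThreshold(gray)
  mask <- if (polarity == "dark_foreground") gray <= t else gray > t
  list(mask = mask, threshold = t)
}

#' Remove small connected components
#'
#' Sets every foreground component with area < \code{minArea} to
#' background (impurity and speck removal); other components are
#' untouched. Idempotent and monotone.
#'
#' @param mask logical matrix.
#' @param minArea minimum area in pixels to keep.
#' @param connectivity 4 or 8 (default 8).
#' @return a logical matrix
#' @export
removeSmallComponents <- function(mask, minArea, connectivity = 8L) {
  stopifnot(is.logical(mask), minArea >= 0)
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  if (minArea == 0 || !any(mask)) return(mask)
  lab <- .cc_label(mask, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minArea)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Default minimum component area for a scene spec
#'
#' 10\% of the expected single-grain area
#' \eqn{\pi (L/2)(L/(2\,AR))} implied by the spec's grain geometry;
#' used as the impurity-removal gate and the watershed fragment gate.
#' Debris blobs blur-dilate to well under this size while the
#' smallest plausible grain (shrunken immature, short end of the
#' length distribution) stays several times above it.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return area in pixels
#' @export
defaultMinArea <- function(spec) {
  L <- spec@grainLengthPx[1]; AR <- spec@aspectRatio[1]
  0.10 * pi * (L / 2) * (L / (2 * AR))
}

#' Scene to clean binary foreground mask
#'
#' The standard preprocessing chain: grayscale conversion, Gaussian
#' denoising, Otsu binarization (dark foreground), small-component
#' removal.
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param sigma Gaussian sigma (px).
#' @param minArea impurity gate in pixels.
#' @param channelWeights see \code{\link{toGray}}.
#' @param polarity see \code{\link{binarizeOtsu}}.
#' @return list with \code{mask}, \code{gray} (denoised), and
#'   \code{threshold}
#' @export
preprocessScene <- function(image, sigma = 1.0, minArea = 12,
                            channelWeights = c(0.299, 0.587, 0.114, 0, 0),
                            polarity = "dark_foreground") {
  gray <- gaussianDenoise(toGray(image, channelWeights), sigma)
  bin <- binarizeOtsu(gray, polarity)
  mask <- removeSmallComponents(bin$mask, minArea)
  list(mask = mask, gray = gray, threshold = bin$threshold)
}
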