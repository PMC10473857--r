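#' @include regions.R
NULL

#' Gradient magnitude of a grayscale image
#'
#' The default \code{"forward_diff"} method is the first-difference
#' magnitude
#' \eqn{g(x,y) = \sqrt{(f(x,y)-f(x-1,y))^2 + (f(x,y)-f(x,y-1))^2}}
#' with a replicated border (difference 0 along the first row and
#' column). A Sobel magnitude with reflected borders is available as
#' an alternative.
#'
#' @param gray numeric matrix, at least 2 x 2.
#' @param method \code{"forward_diff"} or \code{"sobel"}.
#' @return nonnegative numeric matrix of the same dimensions
#' @examples
#' f <- matrix(c(7, 6, 7, 10), 2)  # g(2,2) = sqrt(3^2 + 4^2) = 5
#' gradientMagnitude(f)[2, 2]
#' @export
gradientMagnitude <- function(gray, method = c("forward_diff", "sobel")) {
  method <- match.arg(method)
  if (!is.matrix(gray) || nrow(gray) < 2L || ncol(gray) < 2L)
    stop("gray must be a matrix of at least 2 x 2", call. = FALSE)
  H <- nrow(gray); W <- ncol(gray)
  if (method == "forward_diff") {
    dx <- gray - gray[c(1L, seq_len(H - 1L)), , drop = FALSE]
    dy <- gray - gray[, c(1L, seq_len(W - 1L)), drop = FALSE]
    return(sqrt(dx^2 + dy^2))
  }
  refl <- function(m) {
    m <- rbind(m[1, ], m, m[H, ]); cbind(m[, 1], m, m[, W])
  }
  p <- refl(gray)
  sh <- function(dr, dc) p[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
  gx <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  gy <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  sqrt(gx^2 + gy^2)
}

#' Suppress shallow gradient minima by Otsu clamping
#'
#' Clamps the gradient pixelwise at a threshold,
#' \code{pmax(gradient, t)}: basins shallower than t are flooded away
#' before the watershed runs, which removes the spurious minima that
#' cause over-segmentation while leaving every ridge above t intact.
#' With \code{mode = "otsu"} the threshold is found by Otsu's
#' between-class-variance criterion on the gradient values (binned
#' into 256 equal-width bins over their range), optionally restricted
#' to \code{mask}; with \code{mode = "fixed"} it is supplied.
#'
#' A constant gradient is degenerate; it is returned unchanged with a
#' \code{"degenerate"} attribute set.
#'
#' @param gradient nonnegative numeric matrix.
#' @param mode \code{"otsu"} or \code{"fixed"}.
#' @param threshold clamp level when \code{mode = "fixed"}.
#' @param mask optional logical matrix restricting the pixels entering
#'   the Otsu histogram (the clamp is still applied everywhere).
#' @return the clamped gradient, with attribute \code{"threshold"}
#' @export
suppressMinima <- function(gradient, mode = c("otsu", "fixed"),
                           threshold = NULL, mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(threshold)) stop("fixed mode needs a threshold",
                                 call. = FALSE)
    t <- threshold
  } else {
    v <- if (is.null(mask)) gradient else gradient[mask]
    rng <- range(v)
    if (rng[2] - rng[1] <= 0) {
      out <- gradient
      attr(out, "degenerate") <- TRUE
      attr(out, "threshold") <- rng[1]
      warning("constant gradient: nothing to clamp", call. = FALSE)
      return(out)
    }
    s <- 255 / (rng[2] - rng[1])
    tb <- otsuThreshold((v - rng[1]) * s)
    t <- rng[1] + (tb + 0.5) / s
  }
  out <- pmax(gradient, t)
  attr(out, "threshold") <- t
  out
}

#' Watershed flooding of a gradient restricted to one region
#'
#' Immersion watershed: region pixels are processed by ascending
#' gradient level; at each level the level set is flooded from the
#' existing catchment basins by synchronous breadth-first waves
#' (geodesic influence zones, FIFO within a wave), pixels reached by
#' two basins simultaneously become watershed-line pixels, and
#' unreached level pixels are regional minima seeding new basins.
#'
#' @param gradient numeric matrix covering the region.
#' @param regionMask logical matrix of the same size; pixels to flood.
#' @return a \linkS4class{SplitResult}; its label raster is 0 outside
#'   the region, -1 on watershed lines, k >= 1 per basin. Basins and
#'   lines partition the region pixels.
#' @export
watershedFlood <- function(gradient, regionMask) {
  stopifnot(is.matrix(gradient), is.logical(regionMask),
            identical(dim(gradient), dim(regionMask)))
  if (!any(regionMask))
    stop("regionMask is empty", call. = FALSE)
  lab <- .ws_flood(gradient, regionMask)
  new("SplitResult", labelMatrix = lab, nSegments = max(lab, 0L))
}

# binary erosion by a (2r+1) x (2r+1) square structuring element
.erode_mask <- function(m, r = 2L) {
  for (i in seq_len(r)) {
    m <- m & rbind(m[-1, , drop = FALSE], FALSE) &
      rbind(FALSE, m[-nrow(m), , drop = FALSE]) &
      cbind(m[, -1, drop = FALSE], FALSE) &
      cbind(FALSE, m[, -ncol(m), drop = FALSE])
  }
  m
}

# Merge basins with no bright grain-body pixels into their dominant
# neighbor. A real grain basin always contains body pixels near the
# region's brightness level; a basin whose 0.9 quantile stays below
# 0.7 x the region's upper-quartile gray is made of contact-line or
# defect-spot pixels only, and belongs to an adjacent grain. A basin
# whose *median* is that dark, which borders at least two other
# basins, and which is thin (full width across its narrow axis well
# under a grain's minor width) is the other contact-band signature:
# the band straddles the two grains it separates, and only its rim
# picks up bright transition pixels that lift the upper quantile; the
# thinness requirement keeps whole dark grains sitting in a chain
# (which also border two neighbors) out of the merge. Smallest dark
# basin first; its pixels join the basin owning the most pixels
# within Chebyshev distance 2.
.merge_dark_basins <- function(ws, gray, regionMask,
                               q = 0.9, frac = 0.7) {
  bodyRef <- quantile(gray[regionMask], 0.75, names = FALSE)
  H <- nrow(ws); W <- ncol(ws)
  neigh_cnt <- function(s, mx) {
    pix <- which(ws == s, arr.ind = TRUE)
    cnt <- integer(mx)
    for (dr in -2:2) for (dc in -2:2) {
      rr <- pix[, 1] + dr; cc <- pix[, 2] + dc
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      v <- ws[cbind(rr[ok], cc[ok])]
      v <- v[v > 0L & v != s]
      if (length(v)) cnt <- cnt + tabulate(v, nbins = mx)
    }
    cnt
  }
  repeat {
    mx <- max(ws, 0L)
    if (mx == 0L) break
    areas <- tabulate(ws[ws > 0L], nbins = mx)
    ids <- which(areas > 0L)
    if (length(ids) <= 1L) break
    dark <- ids[vapply(ids, function(i)
      quantile(gray[ws == i], q, names = FALSE) < frac * bodyRef,
      logical(1))]
    if (length(dark) == 0L) {
      # straddling bands: dark core, thin, >= 2 neighboring basins
      thin <- function(i) {
        pix <- which(ws == i, arr.ind = TRUE)
        if (nrow(pix) < 3L) return(TRUE)
        ev <- eigen(stats::cov(pix), symmetric = TRUE,
                    only.values = TRUE)$values
        # 4 sd across the narrow axis ~ full width (2b for an ellipse)
        4 * sqrt(max(min(ev), 0)) <= 6
      }
      cand <- ids[vapply(ids, function(i)
        median(gray[ws == i]) < frac * bodyRef && thin(i), logical(1))]
      for (s in cand[order(areas[cand])]) {
        cnt <- neigh_cnt(s, mx)
        if (sum(cnt > 0L) >= 2L) { dark <- s; break }
      }
      if (length(dark) == 0L) break
    }
    s <- dark[which.min(areas[dark])]
    cnt <- neigh_cnt(s, mx)
    if (all(cnt == 0L)) break
    ws[ws == s] <- which.max(cnt)
  }
  ws
}

#' Split adhered regions into single-grain masks
#'
#' Singles from the triage pass through unchanged. Each adhered region
#' is split by the watershed of its Otsu-clamped gradient. The clamp
#' threshold is estimated per region from the gradient over the
#' region's interior (the region eroded by 2 px): the outer boundary
#' ring carries the grain/background step, whose huge gradients would
#' inflate the Otsu threshold past the shallow ridges separating
#' touching grains. After flooding, basins containing no bright
#' grain-body pixels (contact-line or defect-spot basins), and thin
#' dark-cored bands straddling two neighboring basins (the contact
#' band between touching grains), are merged into their dominant
#' neighbor; submasks smaller than the fragment gate --
#' \code{max(minArea, 0.2 x median single-grain area)}, or 0.2 x the
#' clump's largest basin when the scene has no triaged singles to
#' calibrate against -- are discarded as spurious fragments (boundary
#' pockets of the gradient ring, far below any plausible grain). An
#' adhered
#' region yielding a single basin passes through as one mask and is
#' flagged \code{splitFailed}. Watershed-line pixels belong to no
#' grain.
#'
#' @param gray the denoised grayscale scene the triage was computed on.
#' @param triage a \linkS4class{TriageResult}.
#' @param minArea lower bound of the fragment gate in pixels.
#' @param gradientMethod passed to \code{\link{gradientMagnitude}}.
#' @param clamp logical; Otsu-clamp the gradient (TRUE, the default)
#'   or run the raw watershed (the over-segmentation-prone control).
#' @return a \linkS4class{GrainMasks}
#' @export
splitAdhered <- function(gray, triage, minArea = 12,
                         gradientMethod = "forward_diff", clamp = TRUE) {
  stopifnot(is(triage, "TriageResult"))
  regions <- triage@regions
  labm <- regions@labelMatrix
  H <- nrow(labm); W <- ncol(labm)
  grad <- if (nrow(regions@stats) > 0L)
    gradientMagnitude(gray, gradientMethod) else NULL
  out <- matrix(0L, H, W)
  prov <- list()
  nid <- 0L
  st <- regions@stats
  singleAreas <- st$area[triage@triageClass == "single"]
  fragGate <- if (length(singleAreas) > 0L)
    max(minArea, 0.2 * median(singleAreas)) else minArea
  for (k in seq_len(nrow(st))) {
    lb <- st$label[k]
    r0 <- st$bboxRow0[k] + 1L; r1 <- st$bboxRow1[k]
    c0 <- st$bboxCol0[k] + 1L; c1 <- st$bboxCol1[k]
    sub <- labm[r0:r1, c0:c1, drop = FALSE] == lb
    if (triage@triageClass[k] == "single") {
      nid <- nid + 1L
      out[r0:r1, c0:c1][sub] <- nid
      prov[[length(prov) + 1L]] <-
        data.frame(maskId = nid, parentRegion = lb, fromAdhered = FALSE,
                   splitFailed = FALSE)
      next
    }
    g <- grad[r0:r1, c0:c1, drop = FALSE]
    if (clamp) {
      hm <- .erode_mask(sub, 2L)
      if (sum(hm) < 20L) hm <- sub
      gc <- suppressMinima(g, "otsu", mask = hm)
      if (isTRUE(attr(gc, "degenerate"))) gc <- g
    } else gc <- g
    ws <- .ws_flood(gc, sub)
    ws <- .merge_dark_basins(ws, gray[r0:r1, c0:c1, drop = FALSE], sub)
    nlab <- max(ws, 0L)
    areas <- if (nlab > 0L) tabulate(ws[ws > 0L], nbins = nlab)
    else integer(0)
    if (sum(areas > 0L) <= 1L) {
      nid <- nid + 1L
      out[r0:r1, c0:c1][sub] <- nid
      prov[[length(prov) + 1L]] <-
        data.frame(maskId = nid, parentRegion = lb, fromAdhered = TRUE,
                   splitFailed = TRUE)
      next
    }
    # with no singles in the scene to calibrate against, a clump's
    # own dominant basin stands in for the typical grain area
    gateK <- if (length(singleAreas) > 0L) fragGate
    else max(minArea, 0.2 * max(areas))
    keep <- which(areas >= gateK)
    if (length(keep) == 0L) keep <- which.max(areas)
    for (s in keep) {
      nid <- nid + 1L
      sel <- which(ws == s)
      out[r0:r1, c0:c1][sel] <- nid
      prov[[length(prov) + 1L]] <-
        data.frame(maskId = nid, parentRegion = lb, fromAdhered = TRUE,
                   splitFailed = length(keep) == 1L)
    }
  }
  provdf <- if (length(prov)) do.call(rbind, prov)
  else data.frame(maskId = integer(0), parentRegion = integer(0),
                  fromAdhered = logical(0), splitFailed = logical(0))
  new("GrainMasks", labelMatrix = out, provenance = provdf)
}

#' Segment a scene end to end
#'
#' Preprocessing, region labeling, roundness triage, and watershed
#' splitting in one call.
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param sigma,minArea,channelWeights,polarity see
#'   \code{\link{preprocessScene}}.
#' @param roundnessThreshold,areaGateFactor,widthGateFactor see
#'   \code{\link{triageRegions}}.
#' @param gradientMethod,clamp see \code{\link{splitAdhered}}.
#' @return list with \code{masks} (\linkS4class{GrainMasks}),
#'   \code{triage}, \code{gray}, and \code{mask} (binary foreground)
#' @export
segmentScene <- function(image, sigma = 1.0, minArea = 12,
                         channelWeights = c(0.299, 0.587, 0.114, 0, 0),
                         polarity = "dark_foreground",
                         roundnessThreshold = 0.5, areaGateFactor = 1.35,
                         widthGateFactor = 1.3,
                         gradientMethod = "forward_diff", clamp = TRUE) {
  pre <- preprocessScene(image, sigma, minArea, channelWeights, polarity)
  regions <- labelRegions(pre$mask)
  triage <- triageRegions(regions, roundnessThreshold, areaGateFactor,
                          widthGateFactor)
  masks <- splitAdhered(pre$gray, triage, minArea, gradientMethod, clamp)
  list(masks = masks, triage = triage, gray = pre$gray, mask = pre$mask,
       threshold = pre$threshold)
}
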