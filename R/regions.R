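#' @include preprocess.R
NULL

# Moore boundary tracing of the outer 8-connected boundary of a single
# component given as a logical submask. Returns the closed chain of
# pixel centers (n x 2, row/col).
.trace_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(idx)
  ord <- order(idx[, 2], idx[, 1])
  start <- idx[ord[1L], ]
  nb <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
               ncol = 2, byrow = TRUE)   # clockwise from W
  H <- nrow(mask); W <- ncol(mask)
  cap <- 4L * nrow(idx) + 16L
  chain <- matrix(0L, cap, 2L)
  chain[1L, ] <- start
  nsteps <- 1L
  cur <- start
  b <- 1L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      j <- ((b - 1L + k) %% 8L) + 1L
      p <- cur + nb[j, ]
      if (p[1] >= 1L && p[1] <= H && p[2] >= 1L && p[2] <= W &&
          mask[p[1], p[2]]) {
        nsteps <- nsteps + 1L
        chain[nsteps, ] <- p
        b <- (((j + 4L - 1L) %% 8L) %% 8L) + 2L
        if (b > 8L) b <- b - 8L
        cur <- p
        found <- TRUE
        break
      }
    }
    if (!found) break
    if ((cur[1] == start[1] && cur[2] == start[2]) || nsteps >= cap) break
  }
  chain[seq_len(nsteps), , drop = FALSE]
}

# Boundary-chain perimeter. Default weights are the Kulpa-calibrated
# straight/diagonal step lengths (0.948, 1.343), which remove the
# systematic overestimate of the raw (1, sqrt(2)) chain on digitized
# smooth shapes; the raw convention is available via `weights`.
# An isolated pixel has perimeter 4 (its four cracks); the chain length
# is floored at 4 so degenerate 2-3 pixel regions stay finite.
.chain_perimeter <- function(mask, weights = c(0.948, 1.343)) {
  ch <- .trace_boundary(mask)
  if (nrow(ch) <= 1L) return(4)
  steps <- abs(diff(ch))
  diagonal <- steps[, 1] + steps[, 2] == 2L
  max(sum(ifelse(diagonal, weights[2], weights[1])), 4)
}

#' Label connected foreground regions and compute shape descriptors
#'
#' Labels the connected components of a binary mask (labels dense from
#' 1 in scan order) and computes, per region: area, perimeter of the
#' 8-connected outer boundary chain (calibrated step weights; see
#' Details), the roundness index \eqn{4 \pi A / S^2}, centroid,
#' bounding box (0-based, half-open), and ellipse-fit axis lengths
#' from second central moments.
#'
#' Roundness is 1 for a disc and decreases with elongation or with
#' merging of touching grains, which is what the downstream triage
#' exploits.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param perimeterWeights straight/diagonal boundary step lengths;
#'   default the calibrated (0.948, 1.343), pass \code{c(1, sqrt(2))}
#'   for the raw chain convention.
#' @return a \linkS4class{RegionSet}; empty mask gives 0 regions.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[3:8, 3:8] <- TRUE; m[12:17, 12:17] <- TRUE
#' regionStats(labelRegions(m))$area  # 36 36
#' @export
labelRegions <- function(mask, connectivity = 8L,
                         perimeterWeights = c(0.948, 1.343)) {
  stopifnot(is.logical(mask))
  connectivity <- as.integer(match.arg(as.character(connectivity),
                                       c("8", "4")))
  lab <- .cc_label(mask, connectivity)
  K <- max(lab)
  if (K == 0L) {
    return(new("RegionSet", labelMatrix = lab,
               stats = data.frame(label = integer(0), area = integer(0),
                                  perimeter = numeric(0),
                                  roundness = numeric(0),
                                  centroidRow = numeric(0),
                                  centroidCol = numeric(0),
                                  bboxRow0 = integer(0), bboxCol0 = integer(0),
                                  bboxRow1 = integer(0), bboxCol1 = integer(0),
                                  majorAxis = numeric(0),
                                  minorAxis = numeric(0)),
               connectivity = connectivity))
  }
  pix <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[lab > 0L]
  rows <- split(pix[, 1], lv); cols <- split(pix[, 2], lv)
  stats <- data.frame(label = seq_len(K))
  stats$area <- lengths(rows)
  per <- numeric(K); maj <- numeric(K); mino <- numeric(K)
  cr <- numeric(K); cc <- numeric(K)
  b0 <- integer(K); b1 <- integer(K); b2 <- integer(K); b3 <- integer(K)
  for (k in seq_len(K)) {
    r <- rows[[k]]; cl <- cols[[k]]
    r0 <- min(r); r1 <- max(r); c0 <- min(cl); c1 <- max(cl)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(r - r0 + 1L, cl - c0 + 1L)] <- TRUE
    per[k] <- .chain_perimeter(sub, perimeterWeights)
    cr[k] <- mean(r); cc[k] <- mean(cl)
    b0[k] <- r0 - 1L; b1[k] <- c0 - 1L; b2[k] <- r1; b3[k] <- c1
    # second central moments with the 1/12 pixel-extent term
    mrr <- mean((r - cr[k])^2) + 1 / 12
    mcc <- mean((cl - cc[k])^2) + 1 / 12
    mrc <- mean((r - cr[k]) * (cl - cc[k]))
    tr <- mrr + mcc
    dd <- sqrt(max((mrr - mcc)^2 + 4 * mrc^2, 0))
    maj[k] <- 4 * sqrt(max((tr + dd) / 2, 0))
    mino[k] <- 4 * sqrt(max((tr - dd) / 2, 0))
  }
  stats$perimeter <- per
  stats$roundness <- 4 * pi * stats$area / per^2
  stats$centroidRow <- cr; stats$centroidCol <- cc
  stats$bboxRow0 <- b0; stats$bboxCol0 <- b1
  stats$bboxRow1 <- b2; stats$bboxCol1 <- b3
  stats$majorAxis <- maj; stats$minorAxis <- mino
  new("RegionSet", labelMatrix = lab, stats = stats,
      connectivity = connectivity)
}

#' Roundness index of labeled regions
#'
#' Convenience accessor for \eqn{4 \pi A / S^2} per region.
#'
#' @param regions a \linkS4class{RegionSet}.
#' @return numeric vector of roundness values
#' @export
regionRoundness <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  regions@stats$roundness
}

#' Triage regions into single grains and adhered clumps
#'
#' A region is called adhered when its roundness falls below
#' \code{roundnessThreshold}, or when its area exceeds
#' \code{areaGateFactor} times the median area of the
#' roundness-passing regions, or when its ellipse-fit minor axis
#' exceeds \code{widthGateFactor} times the median minor axis of the
#' roundness-passing regions. The default cut-off 0.5 sits in the gap
#' between a 3:1 single-grain ellipse (roundness about 0.66) and an
#' end-to-end merged pair (about 0.38). The two secondary gates catch
#' the merges the roundness index cannot: side-by-side pairs are
#' nearly as round as a single grain, but are markedly larger and --
#' even when heavy overlap hides the extra area -- markedly wider
#' than any single grain. Both gates are cheap to trip by accident:
#' a single grain misrouted to the watershed comes back as one basin
#' and costs nothing, whereas a clump missed by the triage always
#' costs a grain.
#'
#' @param regions a \linkS4class{RegionSet}.
#' @param roundnessThreshold roundness cut-off in (0, 1.5).
#' @param areaGateFactor multiple of the median single-grain area above
#'   which a region is adhered regardless of roundness.
#' @param widthGateFactor multiple of the median single-grain minor
#'   axis above which a region is adhered regardless of roundness.
#' @return a \linkS4class{TriageResult}
#' @export
triageRegions <- function(regions, roundnessThreshold = 0.5,
                          areaGateFactor = 1.35,
                          widthGateFactor = 1.3) {
  stopifnot(is(regions, "RegionSet"))
  if (roundnessThreshold <= 0 || roundnessThreshold >= 1.5)
    stop("roundnessThreshold must lie in (0, 1.5)", call. = FALSE)
  st <- regions@stats
  if (nrow(st) == 0L)
    return(new("TriageResult", regions = regions,
               triageClass = character(0),
               thresholdUsed = roundnessThreshold, areaGateUsed = Inf,
               widthGateUsed = Inf))
  roundPass <- st$roundness >= roundnessThreshold
  gate <- if (any(roundPass))
    areaGateFactor * median(st$area[roundPass]) else Inf
  wgate <- if (any(roundPass))
    widthGateFactor * median(st$minorAxis[roundPass]) else Inf
  cls <- ifelse(!roundPass | st$area > gate | st$minorAxis > wgate,
                "adhered", "single")
  new("TriageResult", regions = regions, triageClass = cls,
      thresholdUsed = roundnessThreshold, areaGateUsed = gate,
      widthGateUsed = wgate)
}

#' Export per-region statistics with triage classes
#'
#' @param triage a \linkS4class{TriageResult}.
#' @param file optional CSV path; when given the table is written there.
#' @return the per-region data.frame, invisibly when writing
#' @export
regionReport <- function(triage, file = NULL) {
  stopifnot(is(triage, "TriageResult"))
  df <- triage@regions@stats
  df$triageClass <- triage@triageClass
  if (!is.null(file)) {
    write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
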