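#' @include methods.R
NULL

#' Create a scene specification
#'
#' Builds a validated \linkS4class{SceneSpec} describing a backlit
#' multispectral rice scene. The defaults are a desk-scale scene of 100
#' grains; full-scale scenes (800--1000 grains, as a 20 g sample on an
#' inspection stage) are obtained by raising \code{nGrains} and the
#' canvas size together (occupancy should stay below roughly 25\%).
#'
#' @param width,height canvas size in pixels.
#' @param nGrains number of grains.
#' @param adhesionProb probability in [0,1] that a grain is placed
#'   touching an existing grain (forming a cluster of 2+ grains).
#' @param imperfectFrac probability in [0,1] that a grain is imperfect.
#' @param defectMix probabilities over the imperfect phenotypes
#'   (lesion spots, mildew patch, immature/unripe); must sum to 1.
#' @param grainLengthPx mean and sd of the grain major-axis length (px).
#' @param aspectRatio mean and sd of the major/minor axis ratio.
#' @param noiseRate expected salt-noise specks per 1e4 background px.
#' @param impurityCount number of small dark debris blobs.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SceneSpec}
#' @examples
#' sp <- sceneSpec(nGrains = 10, seed = 1)
#' sp
#' @export
sceneSpec <- function(width = 512, height = 512, nGrains = 100,
                      adhesionProb = 0.2, imperfectFrac = 0.3,
                      defectMix = c(lesion = 0.4, mildew = 0.3,
                                    immature = 0.3),
                      grainLengthPx = c(mean = 30, sd = 1.2),
                      aspectRatio = c(mean = 3, sd = 0.18),
                      noiseRate = 2, impurityCount = 5, seed = 1L) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      nGrains = as.integer(nGrains), adhesionProb = adhesionProb,
      imperfectFrac = imperfectFrac,
      defectMix = setNames(as.numeric(defectMix),
                           c("lesion", "mildew", "immature")),
      grainLengthPx = unname(as.numeric(grainLengthPx)),
      aspectRatio = unname(as.numeric(aspectRatio)),
      noiseRate = noiseRate, impurityCount = as.integer(impurityCount),
      seed = as.integer(seed))
}

# Photometric constants of the virtual acquisition rig (backlit stage:
# bright background, darker grains; see the methods vignette).
.RENDER <- list(
  bg = c(R = 230, G = 230, B = 230, NIR1 = 226, NIR2 = 226),
  tau_body_mean = 0.60, tau_body_sd = 0.03,
  tau_channel_offset = c(R = 0.02, G = 0, B = -0.04),
  tau_nir_offset = 0.08,
  edge_brighten = 0.35,   # tau(u2) = tau_c * (1 + 0.35 u2), capped
  tau_cap = 0.93,
  sigma_rgb = 0.5, sigma_nir1 = 2.0, sigma_nir2 = 2.4, nir2_gain = 0.97,
  noise_sd_rgb = 4.0, noise_sd_nir = 1.2,
  lesion_mult_rgb = 0.35, lesion_mult_nir = 0.70,
  mildew_mult_rgb = 0.65, mildew_mult_nir = 0.85,
  immature_tau_shift = 0.12, immature_shrink = c(0.85, 0.95),
  adhesion_gap = c(0.70, 0.95), placement_clearance = 2,
  # light scattered/occluded in the wedge-shaped air gap where two
  # grain surfaces meet: pixels within contact_margin px of both
  # ellipse boundaries are darkened, closing the contact line across
  # the full neck (the overlap lens alone tapers to nothing at its tips)
  contact_margin = 1.0, contact_mult_rgb = 0.35, contact_mult_nir = 0.70,
  max_tries = 200L)

# pixels of a rotated ellipse within the canvas; returns linear indices
# and the normalized squared elliptical radius u2 at each pixel
.ellipse_pixels <- function(H, W, cr, cc, a, b, theta, inflate = 0) {
  ai <- a + inflate; bi <- b + inflate
  r0 <- max(1L, floor(cr - ai)); r1 <- min(H, ceiling(cr + ai))
  c0 <- max(1L, floor(cc - ai)); c1 <- min(W, ceiling(cc + ai))
  if (r0 > r1 || c0 > c1)
    return(list(idx = integer(0), u2 = numeric(0)))
  rs <- r0:r1; cs <- c0:c1
  dr <- rs - cr; dc <- cs - cc
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr * ct, dc * st, "+")          # along major axis
  v <- outer(-dr * st, dc * ct, "+")         # along minor axis
  u2 <- (u / ai)^2 + (v / bi)^2
  keep <- which(u2 <= 1)
  rows <- rep(rs, times = length(cs))[keep]
  cols <- rep(cs, each = length(rs))[keep]
  list(idx = (cols - 1L) * H + rows, u2 = u2[keep],
       rows = rows, cols = cols)
}

# separable Gaussian blur, reflected borders, truncation radius ceil(3*sigma)
.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(x, n) rbind(x[n:1, , drop = FALSE], x,
                              x[nrow(x):(nrow(x) - n + 1L), , drop = FALSE])
  conv1 <- function(x) {
    xp <- pad(x, r)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Generate a synthetic multispectral grain scene
#'
#' Renders rice grains as rotated shaded ellipses on a bright backlit
#' background, with per-channel photometry, defect phenotypes (lesion
#' spots, mildew patches, immature grains), adhesion clusters with a
#' darker contact seam (transmittances of overlapping grains multiply,
#' as for stacked translucent bodies), smoother and less noisy NIR
#' planes, salt-noise specks and impurity blobs. Deterministic given
#' the spec's seed.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return a \linkS4class{GrainScene} holding the noisy image, the
#'   pre-noise rendering, and the exact \linkS4class{SceneGroundTruth}.
#' @examples
#' sc <- generateScene(sceneSpec(nGrains = 5, width = 160, height = 160,
#'                               seed = 7))
#' nGrains(sc)
#' @export
generateScene <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  P <- .RENDER
  H <- spec@height; W <- spec@width; n <- spec@nGrains

  tau <- list(R = matrix(1, H, W), G = matrix(1, H, W),
              B = matrix(1, H, W), N = matrix(1, H, W))
  owner <- matrix(0L, H, W)
  ownerDist <- matrix(Inf, H, W)
  support <- matrix(FALSE, H, W)   # union of grain supports
  blocked <- matrix(FALSE, H, W)   # supports inflated by clearance

  params <- vector("list", n)
  labels <- character(n); defects <- rep(NA_character_, n)
  cluster <- integer(n)

  for (i in seq_len(n)) {
    adhereMode <- i > 1L && runif(1) < spec@adhesionProb
    placed <- FALSE
    for (try in seq_len(P$max_tries)) {
      L <- max(8, rnorm(1, spec@grainLengthPx[1], spec@grainLengthPx[2]))
      AR <- max(1.3, rnorm(1, spec@aspectRatio[1], spec@aspectRatio[2]))
      a <- L / 2; b <- L / (2 * AR)
      imperfect <- runif(1) < spec@imperfectFrac
      defect <- if (imperfect)
        sample(names(spec@defectMix), 1L, prob = spec@defectMix)
      else NA_character_
      if (identical(defect, "immature")) {
        shrink <- runif(1, P$immature_shrink[1], P$immature_shrink[2])
        a <- a * shrink; b <- b * shrink
      }
      if (adhereMode) {
        j <- sample(i - 1L, 1L)
        pj <- params[[j]]
        side <- sample(c(-1, 1), 1L)
        phi <- pj$theta + side * pi / 2 + rnorm(1, 0, 0.17)
        d <- runif(1, P$adhesion_gap[1], P$adhesion_gap[2]) * (b + pj$b)
        cr <- pj$cr + d * cos(phi); cc <- pj$cc + d * sin(phi)
        theta <- pj$theta + rnorm(1, 0, 0.26)
      } else {
        m <- a + 2
        cr <- runif(1, 1 + m, H - m); cc <- runif(1, 1 + m, W - m)
        theta <- runif(1, 0, pi)
      }
      if (cr < a + 1 || cr > H - a || cc < a + 1 || cc > W - a) next
      ep <- .ellipse_pixels(H, W, cr, cc, a, b, theta)
      if (length(ep$idx) == 0L) next
      if (adhereMode) {
        ov <- owner[ep$idx]
        if (any(ov != 0L & ov != j)) next          # touch only the target
        if (!any(ov == j)) next                    # must actually touch it
      } else {
        if (any(blocked[ep$idx])) next
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("placement failure: placed ", i - 1L, " of ", n,
           " grains before exceeding the retry cap; enlarge the canvas ",
           "or reduce nGrains", call. = FALSE)

    # bookkeeping
    labels[i] <- if (is.na(defect)) "perfect" else "imperfect"
    defects[i] <- defect
    cluster[i] <- if (adhereMode) cluster[j] else i
    params[[i]] <- list(cr = cr, cc = cc, a = a, b = b, theta = theta)

    # per-channel body transmittance
    tb <- min(max(rnorm(1, P$tau_body_mean, P$tau_body_sd), 0.50), 0.70)
    if (identical(defect, "immature")) tb <- tb + P$immature_tau_shift
    tch <- c(tb + P$tau_channel_offset, NIR = tb + P$tau_nir_offset)
    prof <- pmin(1 + P$edge_brighten * ep$u2, P$tau_cap / max(tch))

    multRGB <- rep(1, length(ep$idx)); multNIR <- rep(1, length(ep$idx))
    if (identical(defect, "lesion")) {
      for (s in seq_len(sample(3L, 1L))) {
        rho <- sqrt(runif(1, 0, 0.36))      # spot center within u < 0.6
        sang <- runif(1, 0, 2 * pi)
        su <- rho * a * cos(sang); sv <- rho * b * sin(sang)
        scr <- cr + su * cos(theta) - sv * sin(theta)
        scc <- cc + su * sin(theta) + sv * cos(theta)
        srad <- runif(1, 1.5, 3.5)
        drow <- ep$rows - scr; dcol <- ep$cols - scc
        inspot <- (drow^2 + dcol^2) <= srad^2
        multRGB[inspot] <- pmin(multRGB[inspot], P$lesion_mult_rgb)
        multNIR[inspot] <- pmin(multNIR[inspot], P$lesion_mult_nir)
      }
    } else if (identical(defect, "mildew")) {
      frac <- runif(1, 0.2, 0.6)
      s <- sqrt(frac)
      off <- runif(1, 0, (1 - s) * 0.8)
      oang <- runif(1, 0, 2 * pi)
      pcr <- cr + off * a * cos(oang) * cos(theta)
      pcc <- cc + off * a * cos(oang) * sin(theta)
      pp <- .ellipse_pixels(H, W, pcr, pcc, s * a, s * b, theta)
      inpatch <- match(ep$idx, pp$idx)
      hit <- !is.na(inpatch)
      up2 <- pp$u2[inpatch[hit]]
      multRGB[hit] <- P$mildew_mult_rgb + (1 - P$mildew_mult_rgb) * up2
      multNIR[hit] <- P$mildew_mult_nir + (1 - P$mildew_mult_nir) * up2
    }

    tau$R[ep$idx] <- tau$R[ep$idx] * pmin(tch[["R"]] * prof * multRGB, 1)
    tau$G[ep$idx] <- tau$G[ep$idx] * pmin(tch[["G"]] * prof * multRGB, 1)
    tau$B[ep$idx] <- tau$B[ep$idx] * pmin(tch[["B"]] * prof * multRGB, 1)
    tau$N[ep$idx] <- tau$N[ep$idx] * pmin(tch[["NIR"]] * prof * multNIR, 1)

    # contact shading against every earlier grain whose surface comes
    # within contact_margin: intersection of the two ellipses dilated
    # by contact_margin px (applies to deliberate adhesion and to
    # incidental near-contacts alike)
    eb <- NULL
    for (jj in seq_len(i - 1L)) {
      pj <- params[[jj]]
      if (sqrt((cr - pj$cr)^2 + (cc - pj$cc)^2) >
          a + pj$a + 2 * P$contact_margin) next
      if (is.null(eb))
        eb <- .ellipse_pixels(H, W, cr, cc, a, b, theta,
                              inflate = P$contact_margin)
      dr <- eb$rows - pj$cr; dc <- eb$cols - pj$cc
      uj <- dr * cos(pj$theta) + dc * sin(pj$theta)
      vj <- -dr * sin(pj$theta) + dc * cos(pj$theta)
      u2j <- (uj / (pj$a + P$contact_margin))^2 +
        (vj / (pj$b + P$contact_margin))^2
      band <- eb$idx[u2j <= 1]
      if (length(band) == 0L) next
      tau$R[band] <- tau$R[band] * P$contact_mult_rgb
      tau$G[band] <- tau$G[band] * P$contact_mult_rgb
      tau$B[band] <- tau$B[band] * P$contact_mult_rgb
      tau$N[band] <- tau$N[band] * P$contact_mult_nir
    }

    closer <- ep$u2 < ownerDist[ep$idx]
    owner[ep$idx[closer]] <- i
    ownerDist[ep$idx[closer]] <- ep$u2[closer]
    support[ep$idx] <- TRUE
    epb <- .ellipse_pixels(H, W, cr, cc, a, b, theta,
                           inflate = P$placement_clearance)
    blocked[epb$idx] <- TRUE
  }

  # impurity blobs on clear background
  for (k in seq_len(spec@impurityCount)) {
    for (try in seq_len(P$max_tries)) {
      cr <- runif(1, 3, H - 2); cc <- runif(1, 3, W - 2)
      rad <- runif(1, 1.0, 1.7)
      ip <- .ellipse_pixels(H, W, cr, cc, rad, rad * runif(1, 0.6, 1),
                            runif(1, 0, pi))
      if (length(ip$idx) == 0L || any(blocked[ip$idx])) next
      tau$R[ip$idx] <- 0.30; tau$G[ip$idx] <- 0.30; tau$B[ip$idx] <- 0.30
      tau$N[ip$idx] <- 0.65
      break
    }
  }

  clean <- list(
    R = .gblur(P$bg[["R"]] * tau$R, P$sigma_rgb),
    G = .gblur(P$bg[["G"]] * tau$G, P$sigma_rgb),
    B = .gblur(P$bg[["B"]] * tau$B, P$sigma_rgb),
    NIR1 = .gblur(P$bg[["NIR1"]] * tau$N, P$sigma_nir1),
    NIR2 = .gblur(P$bg[["NIR2"]] * tau$N * P$nir2_gain, P$sigma_nir2))
  noiseless <- multiChannelImage(
    r = clean$R, g = clean$G, b = clean$B,
    nir1 = clean$NIR1, nir2 = clean$NIR2)

  nBg <- sum(owner == 0L)
  nSalt <- rbinom(1L, nBg, min(1, spec@noiseRate / 1e4))
  saltIdx <- if (nSalt > 0L) sample(which(owner == 0L), nSalt) else integer(0)
  saltVal <- runif(nSalt, 30, 90)

  noisy <- lapply(names(clean), function(ch) {
    sdn <- if (ch %in% c("NIR1", "NIR2")) P$noise_sd_nir else P$noise_sd_rgb
    m <- clean[[ch]] + matrix(rnorm(H * W, 0, sdn), H, W)
    if (nSalt > 0L) {
      if (ch %in% c("NIR1", "NIR2"))
        m[saltIdx] <- 0.5 * m[saltIdx] + 0.5 * saltVal
      else m[saltIdx] <- saltVal
    }
    pmin(pmax(round(m), 0), 255)
  })
  names(noisy) <- names(clean)
  image <- multiChannelImage(r = noisy$R, g = noisy$G, b = noisy$B,
                             nir1 = noisy$NIR1, nir2 = noisy$NIR2)

  gp <- if (n > 0L) data.frame(
    centerRow = vapply(params, `[[`, 0, "cr"),
    centerCol = vapply(params, `[[`, 0, "cc"),
    semiMajor = vapply(params, `[[`, 0, "a"),
    semiMinor = vapply(params, `[[`, 0, "b"),
    theta = vapply(params, `[[`, 0, "theta"))
  else data.frame(centerRow = numeric(0), centerCol = numeric(0),
                  semiMajor = numeric(0), semiMinor = numeric(0),
                  theta = numeric(0))
  truth <- new("SceneGroundTruth", instanceMask = owner, labels = labels,
               defectTypes = defects, clusterIds = cluster, grainParams = gp)
  new("GrainScene", image = image, noiseless = noiseless, truth = truth,
      spec = spec)
}

#' Write a dataset of generated scenes to disk
#'
#' Generates \code{nScenes} scenes from \code{spec}, using per-scene
#' seeds \code{seed, seed + 1, ...} (a stated counter scheme, so any
#' scene is independently reproducible), and writes for each scene the
#' five channel planes as 8-bit PNG, the instance mask as 16-bit TIFF,
#' the per-grain labels as JSON, plus a dataset manifest JSON.
#'
#' @param nScenes number of scenes.
#' @param spec a \linkS4class{SceneSpec}; its seed is the base seed.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
generateDataset <- function(nScenes, spec, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir))
    stop("cannot create output directory: ", outDir, call. = FALSE)
  scenes <- vector("list", nScenes)
  for (i in seq_len(nScenes)) {
    sp <- spec; sp@seed <- spec@seed + i - 1L
    sc <- generateScene(sp)
    id <- sprintf("scene%03d", i)
    files <- character(0)
    for (ch in .CHANNELS) {
      f <- file.path(outDir, paste0(id, "_", ch, ".png"))
      png::writePNG(getPlane(sc@image, ch) / 255, f)
      files <- c(files, basename(f))
    }
    fm <- file.path(outDir, paste0(id, "_mask.tiff"))
    tiff::writeTIFF(instanceMask(sc) / 65535, fm, bits.per.sample = 16L)
    fl <- file.path(outDir, paste0(id, "_labels.json"))
    jsonlite::write_json(
      list(labels = grainLabels(sc), defectTypes = defectTypes(sc),
           clusterIds = clusterIds(sc), grainParams = grainParams(sc)),
      fl, auto_unbox = FALSE, digits = NA, na = "null")
    scenes[[i]] <- list(id = id, seed = sp@seed, channels = files,
                        mask = basename(fm), labels = basename(fl),
                        nGrains = nGrains(sc))
  }
  manifest <- list(nScenes = nScenes, baseSeed = spec@seed,
                   width = spec@width, height = spec@height,
                   scenes = scenes)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
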