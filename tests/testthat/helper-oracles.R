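# Independent reference implementations ("oracles") used to verify the
# production code. Written for clarity, not speed: plain R loops and
# brute-force search throughout.

# Exhaustive Otsu: try every threshold t in 0..254 and return the first
# argmax of the between-class variance over the floor-binned histogram.
oracle_otsu <- function(x) {
  v <- floor(pmin(pmax(as.numeric(x), 0), 255))
  best <- -Inf
  bestT <- 0L
  for (t in 0:254) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (length(g0) == 0L || length(g1) == 0L) next
    w0 <- length(g0) / length(v)
    w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      bestT <- t
    }
  }
  bestT
}

# Brute-force level-by-level immersion flood. Pixels are processed by
# ascending gradient value; each level set is grown from the existing
# basins in synchronous waves (a wave pixel takes the unique positive
# label among its already-assigned neighbors, or becomes a line pixel
# on conflict or when reachable only through lines); unreached level
# pixels seed one new basin per connected component, in column-major
# scan order of the level set.
oracle_ws_flood <- function(grad, region) {
  H <- nrow(grad)
  W <- ncol(grad)
  lab <- matrix(0L, H, W)
  idx <- which(region)            # column-major, ascending
  if (length(idx) == 0L) return(lab)
  idx <- idx[order(grad[idx])]    # stable sort, ties keep scan order
  neighbors <- function(p) {
    r <- (p - 1L) %% H + 1L
    c <- (p - 1L) %/% H + 1L
    rr <- r + c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    cc <- c + c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    (cc[ok] - 1L) * H + rr[ok]
  }
  nextBasin <- 0L
  lv <- grad[idx]
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j <= length(idx) && lv[j] == lv[i]) j <- j + 1L
    S <- idx[i:(j - 1L)]
    inS <- rep(TRUE, length(S))
    names(inS) <- S
    # wave seeds: level pixels touching anything already assigned
    wave <- S[vapply(S, function(p) any(lab[neighbors(p)] != 0L),
                     logical(1))]
    inS[as.character(wave)] <- FALSE
    while (length(wave) > 0L) {
      wl <- integer(length(wave))
      for (t in seq_along(wave)) {
        ls <- lab[neighbors(wave[t])]
        ls <- unique(ls[ls > 0L])
        wl[t] <- if (length(ls) == 1L) ls else -1L
      }
      lab[wave] <- wl
      nxt <- integer(0)
      for (p in wave) {
        nb <- neighbors(p)
        nb <- nb[!is.na(match(nb, S))]
        nb <- nb[inS[as.character(nb)]]
        inS[as.character(nb)] <- FALSE
        nxt <- c(nxt, nb)
      }
      wave <- nxt
    }
    # new minima: flood-fill each remaining component
    for (p0 in S) {
      if (!inS[as.character(p0)]) next
      nextBasin <- nextBasin + 1L
      stack <- p0
      inS[as.character(p0)] <- FALSE
      lab[p0] <- nextBasin
      while (length(stack) > 0L) {
        p <- stack[length(stack)]
        stack <- stack[-length(stack)]
        nb <- neighbors(p)
        nb <- nb[!is.na(match(nb, S))]
        nb <- nb[inS[as.character(nb)]]
        inS[as.character(nb)] <- FALSE
        lab[nb] <- nextBasin
        stack <- c(stack, nb)
      }
    }
    i <- j
  }
  lab
}

# Are two label rasters the same partition up to label permutation?
# Line pixels (-1) must coincide; each basin of a must map to exactly
# one basin of b and vice versa.
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(which(a == -1L), which(b == -1L))) return(FALSE)
  if (!identical(which(a == 0L), which(b == 0L))) return(FALSE)
  pos <- a > 0L
  key <- paste(a[pos], b[pos])
  length(unique(key)) == length(unique(a[pos])) &&
    length(unique(key)) == length(unique(b[pos]))
}

# Triple-loop direct convolution matching the engine's weight layout:
# row index of W is ky + k*kx + k^2*c (0-based), output (Ho, Wo, F, N).
oracle_conv <- function(X, Wm, b, k, stride, pad) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  nF <- ncol(Wm)
  Xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, N))
  Xp[pad + seq_len(H), pad + seq_len(W), , ] <- X
  Y <- array(0, c(Ho, Wo, nF, N))
  for (n in seq_len(N)) for (f in seq_len(nF))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- b[f]
      for (cc in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k))
        acc <- acc + Wm[(cc - 1L) * k * k + (kx - 1L) * k + ky, f] *
          Xp[(ho - 1L) * stride + ky, (wo - 1L) * stride + kx, cc, n]
      Y[ho, wo, f, n] <- acc
    }
  Y
}

# Ramanujan's ellipse perimeter approximation (first formula).
oracle_ramanujan <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# Render a two-grain clump scene and return its one adhered region
# (gray window, mask) ready for watershed splitting. Returns NULL when
# the pair did not merge into a single region.
make_clump <- function(seed) {
  sc <- generateScene(sceneSpec(width = 96, height = 96, nGrains = 2,
                                adhesionProb = 1, imperfectFrac = 0,
                                noiseRate = 0, impurityCount = 0,
                                seed = seed))
  pre <- preprocessScene(sc@image, minArea = defaultMinArea(sc@spec))
  regions <- labelRegions(pre$mask)
  st <- regionStats(regions)
  if (nrow(st) != 1L) return(NULL)
  # overlap of the true ellipses, relative to the smaller grain
  gp <- sc@truth@grainParams
  ell <- function(k) {
    th <- gp$theta[k]
    outer(1:96, 1:96, function(i, j) {
      u <- (i - gp$centerRow[k]) * cos(th) +
        (j - gp$centerCol[k]) * sin(th)
      v <- -(i - gp$centerRow[k]) * sin(th) +
        (j - gp$centerCol[k]) * cos(th)
      (u / gp$semiMajor[k])^2 + (v / gp$semiMinor[k])^2 <= 1
    })
  }
  m1 <- ell(1); m2 <- ell(2)
  list(gray = pre$gray, mask = pre$mask, scene = sc, regions = regions,
       overlap = sum(m1 & m2) / min(sum(m1), sum(m2)))
}
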