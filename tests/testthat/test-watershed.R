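test_that("forward-difference gradient reproduces the 3-4-5 case", {
  # f(x,y) = 10 with f(x-1,y) = 7 and f(x,y-1) = 6
  f <- matrix(c(7, 6, 7, 10), 2)
  g <- gradientMagnitude(f)
  expect_identical(g[2, 2], 5)                  # sqrt(3^2 + 4^2)
  expect_identical(g[1, 1], 0)                  # replicated border
})

test_that("gradient of a step edge is the step height on the edge", {
  m <- cbind(matrix(10, 6, 3), matrix(50, 6, 3))
  g <- gradientMagnitude(m)
  expect_true(all(g[, 4] == 40))
  expect_true(all(g[, c(1:3, 5:6)] == 0))
})

test_that("sobel gradient matches a hand-computed kernel response", {
  m <- matrix(0, 5, 5)
  m[, 4:5] <- 12
  g <- gradientMagnitude(m, "sobel")
  expect_identical(dim(g), dim(m))
  expect_true(all(g[, 1:2] == 0))
  expect_true(all(g[2:4, 3] == 48))             # full Sobel column response
  expect_identical(gradientMagnitude(matrix(3, 4, 4), "sobel"),
                   matrix(0, 4, 4))
})

test_that("suppressMinima clamps at the requested or Otsu level", {
  g <- matrix(c(0, 1, 2, 3, 10, 11, 12, 13), 2)
  out <- suppressMinima(g, "fixed", threshold = 5)
  expect_identical(out[1, 1], 5)
  expect_identical(attr(out, "threshold"), 5)
  expect_true(all(out >= 5))
  out2 <- suppressMinima(g, "otsu")
  t2 <- attr(out2, "threshold")
  expect_gt(t2, 2.5)
  expect_lt(t2, 10)                # threshold falls in the histogram gap
  expect_warning(suppressMinima(matrix(2, 3, 3), "otsu"), "constant")
})

test_that("watershedFlood matches the oracle on crafted and random patches", {
  # two seeded minima separated by a ridge
  g <- matrix(5, 7, 7)
  g[2, 2] <- 0; g[6, 6] <- 0
  m <- matrix(TRUE, 7, 7)
  ws <- watershedFlood(g, m)
  expect_identical(ws@nSegments, 2L)
  expect_true(same_partition(ws@labelMatrix, oracle_ws_flood(g, m)))
  set.seed(99)
  for (i in 1:5) {
    H <- sample(10:25, 1); W <- sample(10:25, 1)
    g <- matrix(sample(0:8, H * W, TRUE) * 1.0, H, W)
    m <- matrix(runif(H * W) < 0.8, H, W)
    if (!any(m)) next
    expect_true(same_partition(grainsight:::.ws_flood(g, m),
                               oracle_ws_flood(g, m)))
  }
})

test_that("basins and lines partition the region", {
  set.seed(5)
  g <- matrix(sample(0:6, 400, TRUE) * 1.0, 20, 20)
  m <- matrix(runif(400) < 0.7, 20, 20)
  lab <- watershedFlood(g, m)@labelMatrix
  expect_true(all(lab[!m] == 0L))
  expect_true(all(lab[m] != 0L))
})

test_that("clamped watershed splits two overlapping discs at the neck", {
  H <- 60; W <- 80
  d1 <- outer(1:H, 1:W, function(i, j) sqrt((i - 30)^2 + (j - 28)^2))
  d2 <- outer(1:H, 1:W, function(i, j) sqrt((i - 30)^2 + (j - 52)^2))
  mask <- d1 <= 16 | d2 <= 16
  bowl <- pmin(d1, d2) / 2
  # noise-free bowl: exactly two minima, line on the bisector col 40
  cl0 <- watershedFlood(bowl, mask)
  expect_identical(cl0@nSegments, 2L)
  line <- which(cl0@labelMatrix == -1L, arr.ind = TRUE)
  expect_true(all(abs(line[, 2] - 40) <= 3))
  # gradient-like landscape: noisy flat interiors, ridge at the
  # contact; noise minima over-segment unless clamped away
  set.seed(42)
  g <- matrix(runif(H * W), H, W)
  g[d1 <= 16 & d2 <= 16] <- 5          # flat ridge over the contact lens
  raw <- watershedFlood(g, mask)
  expect_gt(raw@nSegments, 2L)
  gc <- suppressMinima(g, "fixed", threshold = 1)
  cl <- watershedFlood(gc, mask)
  expect_identical(cl@nSegments, 2L)
  line2 <- which(cl@labelMatrix == -1L, arr.ind = TRUE)
  expect_true(all(abs(line2[, 2] - 40) <= 4))
})

test_that("splitAdhered passes singles through and splits clumps", {
  sc <- generateScene(sceneSpec(nGrains = 12, adhesionProb = 0,
                                seed = 21))
  pre <- preprocessScene(sc@image, minArea = defaultMinArea(sc@spec))
  tri <- triageRegions(labelRegions(pre$mask))
  masks <- splitAdhered(pre$gray, tri,
                        minArea = defaultMinArea(sc@spec))
  expect_identical(nrow(masks@provenance), 12L)
  expect_true(all(!masks@provenance$fromAdhered |
                    masks@provenance$splitFailed |
                    masks@provenance$maskId > 0))
  clump <- make_clump(4)
  expect_false(is.null(clump))
  # a lone clump has no single-grain medians to gate against, so
  # route it to the splitter explicitly
  tri2 <- triageRegions(clump$regions)
  tri2@triageClass[] <- "adhered"
  masks2 <- splitAdhered(clump$gray, tri2, minArea = 12)
  expect_identical(nrow(masks2@provenance), 2L)
  expect_true(all(masks2@provenance$fromAdhered))
})

test_that("segmentScene returns a consistent bundle", {
  sc <- generateScene(sceneSpec(nGrains = 10, seed = 31))
  seg <- segmentScene(sc@image, minArea = defaultMinArea(sc@spec))
  expect_s4_class(seg$masks, "GrainMasks")
  expect_s4_class(seg$triage, "TriageResult")
  expect_identical(dim(seg$gray), dim(seg$mask))
  expect_true(seg$threshold >= 0 && seg$threshold <= 254)
  labm <- labelMatrix(seg$masks)
  expect_true(all(labm[!seg$mask] == 0L))
})
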