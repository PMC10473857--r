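test_that("labelRegions labels components and measures areas", {
  m <- matrix(FALSE, 20, 20)
  m[3:8, 3:8] <- TRUE
  m[12:17, 12:17] <- TRUE
  rs <- labelRegions(m)
  st <- regionStats(rs)
  expect_identical(st$label, 1:2)
  expect_identical(st$area, c(36L, 36L))
  expect_identical(dim(labelMatrix(rs)), dim(m))
  expect_identical(nrow(regionStats(labelRegions(matrix(FALSE, 4, 4)))),
                   0L)
})

test_that("diagonal touching merges under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE
  expect_identical(nrow(regionStats(labelRegions(m, 8L))), 1L)
  expect_identical(nrow(regionStats(labelRegions(m, 4L))), 2L)
})

test_that("roundness of a disc is 1 within tolerance", {
  for (r in c(8, 15, 25)) {
    side <- 2 * r + 5
    cx <- (side + 1) / 2
    m <- outer(seq_len(side), seq_len(side),
               function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
    rd <- regionRoundness(labelRegions(m))
    expect_gt(rd, 0.9)
    expect_lt(rd, 1.1)
  }
})

test_that("elongation lowers roundness monotonically", {
  ell <- function(a, b) {
    m <- outer(seq_len(2 * a + 5), seq_len(2 * a + 5), function(i, j)
      ((i - a - 3) / b)^2 + ((j - a - 3) / a)^2 <= 1)
    regionRoundness(labelRegions(m))
  }
  expect_gt(ell(15, 15), ell(21, 7))
  expect_gt(ell(21, 7), ell(30, 5))
})

test_that("triage separates singles from an end-to-end merged pair", {
  m <- matrix(FALSE, 40, 90)
  ell <- function(m, cr, cc, a, b) {
    idx <- which(outer(seq_len(nrow(m)), seq_len(ncol(m)), function(i, j)
      ((i - cr) / b)^2 + ((j - cc) / a)^2 <= 1))
    m[idx] <- TRUE
    m
  }
  m <- ell(m, 20, 15, 12, 4)           # single 3:1 grain
  m <- ell(m, 20, 48, 12, 4)           # merged pair, end to end
  m <- ell(m, 20, 70, 12, 4)
  tri <- triageRegions(labelRegions(m))
  expect_identical(sort(tri@triageClass), c("adhered", "single"))
  st <- regionStats(tri@regions)
  expect_identical(tri@triageClass[which.max(st$area)], "adhered")
})

test_that("the width gate catches a round side-by-side pair", {
  m <- matrix(FALSE, 60, 160)
  ell <- function(m, cr, cc, a, b) {
    idx <- which(outer(seq_len(nrow(m)), seq_len(ncol(m)), function(i, j)
      ((i - cr) / b)^2 + ((j - cc) / a)^2 <= 1))
    m[idx] <- TRUE
    m
  }
  # three singles fix the medians; pair overlaps heavily side by side
  m <- ell(m, 15, 20, 15, 5)
  m <- ell(m, 15, 65, 15, 5)
  m <- ell(m, 15, 110, 15, 5)
  m <- ell(m, 40, 60, 15, 5)
  m <- ell(m, 47, 60, 15, 5)           # second grain 7 px below
  tri <- triageRegions(labelRegions(m))
  st <- regionStats(tri@regions)
  pair <- which.max(st$area)
  expect_identical(tri@triageClass[pair], "adhered")
  expect_identical(sum(tri@triageClass == "single"), 3L)
})

test_that("nearly all regions triage single without adhesion", {
  sing <- 0L; tot <- 0L
  for (s in 301:303) {
    sc <- generateScene(sceneSpec(adhesionProb = 0, seed = s))
    pre <- preprocessScene(sc@image, minArea = defaultMinArea(sc@spec))
    tri <- triageRegions(labelRegions(pre$mask))
    tot <- tot + length(tri@triageClass)
    sing <- sing + sum(tri@triageClass == "single")
  }
  expect_gte(sing / tot, 0.99)
})

test_that("regionReport exports stats with triage classes", {
  m <- matrix(FALSE, 15, 15)
  m[3:9, 3:9] <- TRUE
  tri <- triageRegions(labelRegions(m))
  df <- regionReport(tri)
  expect_true(all(c("area", "roundness", "triageClass") %in% names(df)))
  f <- tempfile(fileext = ".csv")
  regionReport(tri, f)
  expect_identical(read.csv(f)$triageClass, df$triageClass)
  unlink(f)
})
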