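test_that("toGray applies the channel weights exactly", {
  pl <- array(0, c(2, 2, 5))
  pl[, , 1] <- 60; pl[, , 2] <- 120; pl[, , 3] <- 180
  pl[, , 4] <- 10; pl[, , 5] <- 250
  img <- multiChannelImage(pl)
  expect_true(all(toGray(img, c(1, 1, 1, 0, 0) / 3) == 120))
  expect_true(all(toGray(img, c(0, 0, 0, 1, 0)) == 10))
  g <- toGray(img)   # Rec.601 on RGB
  expect_true(all(g == floor(0.299 * 60 + 0.587 * 120 + 0.114 * 180 + 0.5)))
  expect_error(toGray(img, c(1, 1, 0, 0, 0)), "summing to 1")
})

test_that("gaussianDenoise preserves constants and flattens noise", {
  m <- matrix(7, 12, 12)
  expect_equal(gaussianDenoise(m, 1.5), m)
  expect_identical(gaussianDenoise(m, 0), m)
  set.seed(1)
  n <- matrix(rnorm(400), 20, 20)
  expect_lt(sd(gaussianDenoise(n, 2)), sd(n) / 2)
  expect_error(gaussianDenoise(m, -1), ">= 0")
})

test_that("otsuThreshold equals the brute-force oracle on edge cases", {
  expect_identical(otsuThreshold(c(rep(10, 5), rep(200, 5))), 10L)
  set.seed(2)
  x <- c(rnorm(300, 60, 10), rnorm(300, 190, 15))
  expect_identical(otsuThreshold(x), oracle_otsu(x))
  expect_error(otsuThreshold(rep(5, 10)), "degenerate")
})

test_that("binarizeOtsu respects polarity", {
  g <- matrix(c(rep(20, 8), rep(230, 8)), 4, 4)
  b <- binarizeOtsu(g, "dark_foreground")
  expect_identical(b$mask, g <= b$threshold)
  b2 <- binarizeOtsu(g, "bright_foreground")
  expect_identical(b2$mask, !b$mask)
})

test_that("removeSmallComponents is a monotone idempotent filter", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE          # area 4
  m[6:9, 6:9] <- TRUE          # area 16
  r <- removeSmallComponents(m, 5)
  expect_identical(sum(r), 16L)
  expect_identical(removeSmallComponents(r, 5), r)   # idempotent
  expect_true(all(r <= m))                           # monotone
  expect_identical(removeSmallComponents(m, 0), m)
})

test_that("preprocessScene isolates grains on a clean scene", {
  sc <- generateScene(sceneSpec(nGrains = 8, adhesionProb = 0,
                                noiseRate = 5, impurityCount = 5,
                                seed = 11))
  pre <- preprocessScene(sc@image, minArea = defaultMinArea(sc@spec))
  regions <- labelRegions(pre$mask)
  expect_identical(nrow(regionStats(regions)), 8L)
  # every region overlaps exactly one true grain
  inst <- instanceMask(sc)
  labm <- labelMatrix(regions)
  for (k in regionStats(regions)$label) {
    gts <- table(inst[labm == k & inst > 0])
    expect_identical(sum(gts >= 10), 1L)
  }
})
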