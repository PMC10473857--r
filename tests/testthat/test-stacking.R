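test_that("stackFive assembles planes in R, G, B, NIR1, NIR2 order", {
  mk <- function(v) matrix(v, 4, 6)
  img <- stackFive(mk(1), mk(2), mk(3), g = mk(4), b = mk(5))
  expect_s4_class(img, "MultiChannelImage")
  expect_identical(dim(img@planes), c(4L, 6L, 5L))
  expect_identical(unname(img@planes[1, 1, ]), c(1, 4, 5, 2, 3))
  rgb <- array(0, c(4, 6, 3)); rgb[, , 1] <- 9
  img2 <- stackFive(rgb, mk(2), mk(3))
  expect_identical(getPlane(img2, "R"), mk(9))
  expect_error(stackFive(array(0, c(4, 6, 2)), mk(1), mk(2)), "H, W, 3")
})

test_that("bilinear resize is exact for identity and constants", {
  m <- matrix(runif(48), 6, 8)
  expect_equal(grainsight:::.resize_bilinear(m, 6, 8), m)
  up <- grainsight:::.resize_bilinear(matrix(3.5, 4, 4), 11, 9)
  expect_identical(dim(up), c(11L, 9L))
  expect_true(all(abs(up - 3.5) < 1e-12))
})

test_that("cropGrain yields a 100x100x5 8-bit crop with zero background", {
  sc <- generateScene(sceneSpec(nGrains = 1, width = 72, height = 72,
                                adhesionProb = 0, noiseRate = 0,
                                seed = 6))
  mask <- instanceMask(sc) == 1L
  cr <- cropGrain(sc@image, mask)
  expect_identical(dim(cr), c(100L, 100L, 5L))
  expect_true(all(cr == round(cr) & cr >= 0 & cr <= 255))
  # zero fill leaves the corners empty for an interior grain
  expect_identical(unname(cr[1, 1, 1]), 0)
  cr2 <- cropGrain(sc@image, mask, backgroundFill = "scene_background")
  expect_gt(cr2[1, 1, 1], 150)           # backlit background is bright
  expect_error(cropGrain(sc@image, mask & FALSE), "empty")
})

test_that("extractCrops returns one crop per mask with metadata", {
  sc <- generateScene(sceneSpec(nGrains = 6, adhesionProb = 0, seed = 9))
  seg <- segmentScene(sc@image, minArea = defaultMinArea(sc@spec))
  crops <- extractCrops(sc@image, seg$masks, scene = "demo")
  expect_s4_class(crops, "GrainCropSet")
  expect_identical(dim(crops@tensor), c(100L, 100L, 5L, 6L))
  expect_identical(nrow(crops@info), 6L)
  expect_true(all(crops@info$scene == "demo"))
})

test_that("generateCropSet balances classes deterministically", {
  a <- generateCropSet(8, seed = 3)
  b <- generateCropSet(8, seed = 3)
  expect_identical(a@tensor, b@tensor)
  tab <- table(a@info$label)
  expect_identical(as.integer(tab[["perfect"]]), 4L)
  expect_identical(as.integer(tab[["imperfect"]]), 4L)
  expect_true(all(is.na(a@info$defectType[a@info$label == "perfect"])))
})

test_that("writeCrops round-trips the tensor through 5-page TIFFs", {
  crops <- generateCropSet(2, seed = 13)
  out <- tempfile("crops")
  writeCrops(crops, out)
  csv <- read.csv(file.path(out, "crops.csv"))
  expect_identical(nrow(csv), 2L)
  pg <- tiff::readTIFF(file.path(out, csv$file[1]), all = TRUE)
  expect_identical(length(pg), 5L)
  expect_equal(round(pg[[3]] * 255), crops@tensor[, , 3, 1],
               ignore_attr = TRUE)
  unlink(out, recursive = TRUE)
})
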