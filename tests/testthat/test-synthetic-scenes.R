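test_that("spec with no adhesion yields exactly nGrains instance labels", {
  sc <- generateScene(sceneSpec(nGrains = 10, adhesionProb = 0, seed = 1))
  labs <- setdiff(unique(as.vector(instanceMask(sc))), 0L)
  expect_setequal(labs, 1:10)
})

test_that("scene generation is deterministic in the seed", {
  a <- generateScene(sceneSpec(nGrains = 15, seed = 7))
  b <- generateScene(sceneSpec(nGrains = 15, seed = 7))
  expect_identical(a@image@planes, b@image@planes)
  expect_identical(instanceMask(a), instanceMask(b))
  c <- generateScene(sceneSpec(nGrains = 15, seed = 8))
  expect_false(identical(a@image@planes, c@image@planes))
})

test_that("scenes carry five planes of 8-bit intensities", {
  sc <- generateScene(sceneSpec(nGrains = 5, seed = 2))
  d <- dim(sc@image@planes)
  expect_identical(d[3], 3L + 2L)
  expect_true(all(sc@image@planes >= 0 & sc@image@planes <= 255))
  expect_identical(channelNames(sc@image),
                   c("R", "G", "B", "NIR1", "NIR2"))
})

test_that("ground truth is internally consistent", {
  sc <- generateScene(sceneSpec(nGrains = 20, seed = 3))
  n <- nGrains(sc)
  expect_identical(length(grainLabels(sc)), n)
  expect_identical(length(defectTypes(sc)), n)
  expect_identical(length(clusterIds(sc)), n)
  expect_true(all(grainLabels(sc) %in% c("perfect", "imperfect")))
  expect_true(all(is.na(defectTypes(sc)[grainLabels(sc) == "perfect"])))
  expect_true(all(defectTypes(sc)[grainLabels(sc) == "imperfect"] %in%
                    c("lesion", "mildew", "immature")))
  expect_true(all(unique(as.vector(instanceMask(sc))) %in% 0:n))
})

test_that("grains are darker than the backlit background", {
  sc <- generateScene(sceneSpec(nGrains = 10, adhesionProb = 0,
                                noiseRate = 0, seed = 4))
  r <- getPlane(sc@image, "R")
  inst <- instanceMask(sc)
  expect_gt(mean(r[inst == 0L]), 200)
  expect_lt(mean(r[inst > 0L]), mean(r[inst == 0L]) - 30)
})

test_that("adhesion produces multi-grain clusters", {
  sc <- generateScene(sceneSpec(nGrains = 40, adhesionProb = 0.5,
                                seed = 5))
  expect_gt(max(table(clusterIds(sc))), 1)
})

test_that("generateDataset writes scene files and a manifest", {
  out <- tempfile("scenes")
  generateDataset(2, sceneSpec(nGrains = 5, seed = 1), out)
  mf <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(mf$nScenes, 2L)
  for (sc in mf$scenes) {
    for (f in sc$channels)
      expect_true(file.exists(file.path(out, f)))
    expect_true(file.exists(file.path(out, sc$mask)))
    expect_true(file.exists(file.path(out, sc$labels)))
  }
  unlink(out, recursive = TRUE)
})
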