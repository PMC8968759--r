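test_that("sampleTrainingPatches draws the requested count from admissible FOV centres", {
  img <- smallPhantom()
  fm <- smallFeatureMap()
  ps <- sampleTrainingPatches(fm, gtMask(img), fovMask(img),
                              nPatches = 120L, size = 64L, seed = 5)
  expect_identical(nPatches(ps), 120L)
  expect_identical(dim(patchInputs(ps)), c(64L, 64L, 3L, 120L))
  expect_identical(dim(patchLabels(ps)), c(64L, 64L, 120L))
  # every patch centre lies on fov == 1 and patches fit inside the raster
  co <- patchCoords(ps)
  H <- dim(imageData(img))[1]; W <- dim(imageData(img))[2]
  expect_true(all(co >= 1))
  expect_true(all(co[, 1] + 63 <= H & co[, 2] + 63 <= W))
  centres <- cbind(co[, 1] + 32, co[, 2] + 32)
  expect_true(all(fovMask(img)[centres] == 1))
  # label patches are crops of the ground truth at the same coordinates
  for (i in c(1, 60, 120)) {
    expect_identical(patchLabels(ps)[, , i],
                     gtMask(img)[co[i, 1] + 0:63, co[i, 2] + 0:63])
    expect_identical(patchInputs(ps)[, , , i],
                     featurePlanes(fm)[co[i, 1] + 0:63, co[i, 2] + 0:63, ])
  }
})

test_that("a DRIVE-scale raster yields the full 500 default patches", {
  img <- smallPhantom()
  fm <- smallFeatureMap()
  ps <- sampleTrainingPatches(fm, gtMask(img), fovMask(img), seed = 1)
  expect_identical(nPatches(ps), 500L)
})

test_that("patch sampling is seed-reproducible and seed-sensitive", {
  img <- smallPhantom()
  fm <- smallFeatureMap()
  draw <- function(s) patchCoords(
    sampleTrainingPatches(fm, gtMask(img), fovMask(img), nPatches = 50L,
                          seed = s))
  expect_identical(draw(7), draw(7))
  expect_false(identical(draw(7), draw(8)))
  # too-small FOV: no admissible centre
  tiny <- new("FeatureMap", planes = array(0.5, c(40, 40, 3)),
              sourceId = "tiny")
  expect_error(
    sampleTrainingPatches(tiny, matrix(0, 40, 40), matrix(1, 40, 40),
                          size = 64L, seed = 1),
    "admissible")
})

test_that("augmentFlips quadruples the set and preserves input/label alignment", {
  img <- smallPhantom()
  fm <- smallFeatureMap()
  ps <- sampleTrainingPatches(fm, gtMask(img), fovMask(img), nPatches = 25L,
                              seed = 3)
  aug <- augmentFlips(ps)
  expect_identical(nPatches(aug), 100L)
  n <- nPatches(ps)
  # variant blocks: identity, horizontal, vertical, both
  i <- 7
  expect_identical(patchInputs(aug)[, , , i], patchInputs(ps)[, , , i])
  expect_identical(patchInputs(aug)[, , , n + i],
                   patchInputs(ps)[, 64:1, , i])
  expect_identical(patchInputs(aug)[, , , 2 * n + i],
                   patchInputs(ps)[64:1, , , i])
  expect_identical(patchInputs(aug)[, , , 3 * n + i],
                   patchInputs(ps)[64:1, 64:1, , i])
  expect_identical(patchLabels(aug)[, , n + i], patchLabels(ps)[, 64:1, i])
  # vessel-pixel count of every label patch is flip-invariant
  counts <- apply(patchLabels(aug), 3, sum)
  expect_identical(counts, rep(apply(patchLabels(ps), 3, sum), 4))
  # flipping twice recovers the original
  expect_identical(patchInputs(aug)[, 64:1, , n + i],
                   patchInputs(ps)[, , , i])
})

test_that("splitTrainVal partitions patches 90/10 reproducibly", {
  img <- smallPhantom()
  fm <- smallFeatureMap()
  ps <- augmentFlips(
    sampleTrainingPatches(fm, gtMask(img), fovMask(img), nPatches = 100L,
                          seed = 2))
  sp <- splitTrainVal(ps, 0.1, seed = 9)
  expect_identical(sum(patchSplit(sp) == "val"), 40L)     # round(400 * 0.1)
  expect_identical(sum(patchSplit(sp) == "train"), 360L)
  expect_true(all(patchSplit(sp) %in% c("train", "val")))
  expect_identical(patchSplit(splitTrainVal(ps, 0.1, seed = 9)),
                   patchSplit(sp))
  expect_error(splitTrainVal(ps, 0), "between")
  expect_error(splitTrainVal(ps, 1), "between")
})

test_that("tileImage covers the raster disjointly and reassembleTiles inverts it", {
  # DRIVE test-image dimensions: 768 x 584 -> 12 x 10 = 120 tiles
  set.seed(4)
  x <- matrix(runif(768 * 584), 768, 584)
  tl <- tileImage(x, 64L)
  expect_length(tl$tiles, 120)
  expect_identical(reassembleTiles(tl$tiles, tl$geometry), x)

  # already-aligned raster: single tile, no padding
  y <- matrix(runif(64 * 64), 64, 64)
  t1 <- tileImage(y, 64L)
  expect_length(t1$tiles, 1)
  expect_identical(t1$geometry@padBottom, 0L)
  expect_identical(t1$geometry@padRight, 0L)
  expect_identical(t1$tiles[[1]], y)

  # round trip is exact over random awkward shapes
  for (i in 1:6) {
    H <- sample(65:200, 1); W <- sample(65:200, 1)
    z <- matrix(runif(H * W), H, W)
    tz <- tileImage(z, 64L)
    expect_identical(reassembleTiles(tz$tiles, tz$geometry), z)
    # disjoint cover of the padded raster
    geom <- tz$geometry
    expect_identical(nrow(geom@coords) * 64L * 64L,
                     (H + geom@padBottom) * (W + geom@padRight))
  }

  # constant tiles reassemble to a constant raster
  ones <- replicate(120, matrix(1, 64, 64), simplify = FALSE)
  expect_identical(reassembleTiles(ones, tl$geometry), matrix(1, 768, 584))
  expect_error(reassembleTiles(tl$tiles[-1], tl$geometry), "count")
})

test_that("3-plane feature maps tile and reassemble consistently", {
  fm <- smallFeatureMap()
  tl <- tileImage(fm, 64L)
  expect_identical(dim(tl$tiles[[1]]), c(64L, 64L, 3L))
  # reassembling any single plane recovers that plane
  plane2 <- lapply(tl$tiles, function(t) t[, , 2])
  expect_identical(reassembleTiles(plane2, tl$geometry),
                   featurePlanes(fm)[, , 2])
})
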