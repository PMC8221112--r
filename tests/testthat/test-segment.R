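# Projection, nuclear segmentation and feature extraction.

test_that("maximum-intensity projection has max-over-z semantics", {
  arr <- array(0, c(4, 4, 3, 2))
  arr[2, 2, 1, 1] <- 1; arr[2, 2, 2, 1] <- 2; arr[2, 2, 3, 1] <- 3
  arr[1, 4, 2, 2] <- 7
  img <- multichannelImage(arr, c("a", "b"), 1, zStep = 1)
  flat <- projectMIP(img)
  expect_false(isStack(flat))
  expect_identical(channelNames(flat), c("a", "b"))
  expect_equal(getChannel(flat, "a")[2, 2], 3)
  expect_equal(getChannel(flat, "b")[1, 4], 7)
  # one informative slice -> that slice; projecting a plane warns
  one <- multichannelImage(array(arr[, , 2, , drop = TRUE], c(4, 4, 1, 2)),
                           c("a", "b"), 1, zStep = 1)
  expect_equal(projectMIP(one)@data, arr[, , 2, ])
  expect_warning(projectMIP(flat), "single plane")
})

test_that("a blank nuclear channel yields an empty label map with a warning", {
  img <- multichannelImage(array(0, c(50, 50, 1)), "DNA", 1)
  expect_warning(lab <- segmentNuclei(img, "DNA"), "empty foreground")
  expect_identical(max(labelData(lab)), 0L)
  expect_identical(nrow(cellData(extractFeatures(lab, img))), 0L)
})

test_that("non-finite nuclear pixels are rejected", {
  img <- multichannelImage(array(1, c(20, 20, 1)), "DNA", 1)
  img@data[3, 3, 1] <- NaN
  expect_error(segmentNuclei(img, "DNA"), "non-finite")
})

test_that("nucleus counts are recovered within 5% at default density", {
  cfg <- flatSceneConfig(field = 500, density = 2000, seed = 13)
  gt <- buildScene(cfg)
  img <- renderScene(gt, defaultOptics())
  lab <- segmentNuclei(img, "DNA")
  nTrue <- nrow(groundTruthCells(gt))
  expect_lt(abs(max(labelData(lab)) - nTrue) / nTrue, 0.05)
})

test_that("watershed splitting separates touching nuclei", {
  # two nuclei r = 3 um with centres 5 um apart form one binary blob
  arr <- array(0, c(40, 40, 1))
  for (c0 in list(c(20, 17), c(20, 22))) {
    idx <- HistoCyto:::diskIndices(40, 40, c0[1], c0[2], 3)
    arr[idx] <- 200
  }
  img <- multichannelImage(arr, "DNA", 1)
  split <- segmentNuclei(img, "DNA", smooth_sigma_um = 0.4,
                         watershed_tolerance = 0.2)
  merged <- segmentNuclei(img, "DNA", split = FALSE)
  expect_identical(max(labelData(split)), 2L)
  expect_identical(max(labelData(merged)), 1L)
})

test_that("features follow the pixel-centre conventions", {
  lab <- matrix(0L, 30, 30)
  lab[1:10, 1:10] <- 1L
  img <- multichannelImage(array(7, c(30, 30, 1)), "m", 0.5)
  cells <- cellData(extractFeatures(new("LabelMap", labels = lab,
                                        pixelSize = 0.5), img))
  expect_equal(cells$mean_m, 7)
  expect_equal(cells$volume_um2, 25)     # 100 px * 0.25 um^2
  # centres at (0-based index + 0.5) * pixel size
  expect_equal(cells$x_um, 2.5)
  expect_equal(cells$y_um, 2.5)
})

test_that("circularity ranks a disk above an equal-area bar", {
  H <- 90
  lab <- matrix(0L, H, H)
  lab[HistoCyto:::diskIndices(H, H, 15, 15, 10)] <- 1L
  diskArea <- sum(lab == 1L)
  barW <- 4
  barLen <- ceiling(diskArea / barW)
  lab[41:(40 + barW), 1:barLen] <- 2L
  img <- multichannelImage(array(0, c(H, H, 1)), "m", 1)
  cells <- cellData(extractFeatures(new("LabelMap", labels = lab,
                                        pixelSize = 1), img))
  expect_gte(cells$sphericity[1], 0.85)
  expect_lt(cells$sphericity[2], cells$sphericity[1])
  expect_true(all(cells$sphericity > 0 & cells$sphericity <= 1.05))
})

test_that("mean intensities are linear in the channel scale", {
  fx <- follicleFixture()
  scaled <- fx$img
  k <- 3.25
  idx <- HistoCyto:::.channelIndex(scaled, "CD20")
  scaled@data[, , idx] <- scaled@data[, , idx] * k
  c1 <- cellData(extractFeatures(fx$labels, fx$img))
  c2 <- cellData(extractFeatures(fx$labels, scaled))
  expect_equal(c2$mean_CD20, k * c1$mean_CD20, tolerance = 1e-12)
  expect_equal(c2$mean_CD4, c1$mean_CD4)
})

test_that("segmentation is equivariant under whole-pixel translations", {
  cfg <- flatSceneConfig(field = 300, density = 1500, seed = 17)
  gt <- buildScene(cfg)
  img <- renderScene(gt, quietOptics())
  dy <- 7L; dx <- 11L
  H <- dim(img@data)[1]; W <- dim(img@data)[2]
  shifted <- img
  shifted@data[] <- 0
  shifted@data[(dy + 1):H, (dx + 1):W, ] <- img@data[1:(H - dy), 1:(W - dx), ]
  # fix the threshold so the zero border of the shifted frame cannot move it
  f1 <- cellData(extractFeatures(segmentNuclei(img, "DNA", threshold = 50, split = FALSE), img))
  f2 <- cellData(extractFeatures(segmentNuclei(shifted, "DNA", threshold = 50, split = FALSE), shifted))
  # compare within a common interior window of the shifted content
  a <- f1[f1$y_um > 10 & f1$y_um < H - dy - 10 &
            f1$x_um > 10 & f1$x_um < W - dx - 10, ]
  a <- a[order(a$y_um, a$x_um), ]
  b <- f2[f2$y_um > 10 + dy & f2$y_um < H - 10 &
            f2$x_um > 10 + dx & f2$x_um < W - 10, ]
  b <- b[order(b$y_um, b$x_um), ]
  expect_identical(nrow(a), nrow(b))
  expect_equal(b$y_um, a$y_um + dy, tolerance = 1e-9)
  expect_equal(b$x_um, a$x_um + dx, tolerance = 1e-9)
})
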