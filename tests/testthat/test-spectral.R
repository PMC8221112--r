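# Spillover estimation, compensation and autofluorescence subtraction.

test_that("identity spillover is recovered exactly from clean single stains", {
  gt <- buildScene(flatSceneConfig(field = 250, density = 1500))
  singles <- renderSingleStains(gt, quietOptics())
  est <- estimateSpillover(singles)
  m <- spilloverCoefficients(est)
  expect_lt(max(abs(m - diag(3))), 1e-6)
})

test_that("a known mixing matrix is recovered within 0.02 under mild noise", {
  gt <- buildScene(flatSceneConfig(field = 400, density = 2000))
  M <- testSpillover(off = 0.15)
  singles <- renderSingleStains(gt, defaultOptics(spill = M))
  est <- estimateSpillover(singles)
  expect_lt(max(abs(spilloverCoefficients(est) - spilloverCoefficients(M))),
            0.02)
})

test_that("an all-background single stain raises an estimation error", {
  gt <- buildScene(flatSceneConfig(field = 200, density = 1200))
  singles <- renderSingleStains(gt, quietOptics())
  blank <- singles[["CD4"]]
  blank@data[] <- 0
  singles[["CD4"]] <- blank
  expect_error(estimateSpillover(singles), "CD4")
})

test_that("estimation is invariant to rescaling a single stain", {
  gt <- buildScene(flatSceneConfig(field = 300, density = 1500))
  M <- testSpillover(off = 0.12)
  singles <- renderSingleStains(gt, quietOptics(spill = M))
  est1 <- estimateSpillover(singles)
  singles[["DNA"]]@data <- singles[["DNA"]]@data * 3.7
  est2 <- estimateSpillover(singles)
  expect_equal(spilloverCoefficients(est1), spilloverCoefficients(est2),
               tolerance = 1e-6)
})

test_that("compensating with the identity matrix is a no-op", {
  gt <- buildScene(flatSceneConfig(field = 150, density = 1000))
  img <- renderScene(gt, quietOptics())
  out <- compensate(img, identitySpillover())
  expect_equal(out@data, img@data)
  expect_true(out@metadata$compensated)
  expect_false(isTRUE(img@metadata$compensated))
})

test_that("compensation inverts mixing on noiseless data", {
  gt <- buildScene(flatSceneConfig(field = 250, density = 1500))
  M <- testSpillover(off = 0.18)
  pure <- renderScene(gt, quietOptics())
  mixed <- renderScene(gt, quietOptics(spill = M))
  rec <- compensate(mixed, M)
  rel <- max(abs(rec@data - pure@data)) / max(pure@data)
  expect_lt(rel, 1e-3)
  # algebraic round trip: re-mixing recovers the observed image
  d <- dim(rec@data)
  remixed <- matrix(rec@data, ncol = d[3]) %*% spilloverCoefficients(M)
  expect_equal(as.numeric(remixed), as.numeric(mixed@data),
               tolerance = 1e-6)
})

test_that("channel-order mismatch is a configuration error", {
  img <- multichannelImage(array(1, c(4, 4, 2)), c("A", "B"), 1)
  m <- diag(2); dimnames(m) <- list(c("B", "A"), c("B", "A"))
  expect_error(compensate(img, spilloverMatrix(m)), "channel order")
})

test_that("autofluorescence subtraction follows the channel arithmetic contract", {
  arr <- array(0, c(5, 5, 3))
  arr[, , 1] <- 4            # AF channel
  arr[, , 2] <- 8            # exactly 2x AF
  arr[, , 3] <- 1            # driven negative by subtraction
  img <- multichannelImage(arr, c("AF", "ch2", "ch3"), 1)
  out0 <- subtractAutofluorescence(img, "AF", c(ch2 = 0, ch3 = 0))
  expect_equal(out0@data, img@data)
  out <- subtractAutofluorescence(img, "AF", c(ch2 = 2, ch3 = 2))
  expect_true(all(getChannel(out, "ch2") == 0))
  expect_true(all(getChannel(out, "ch3") == 0))          # clamped, not negative
  expect_equal(getChannel(out, "AF"), getChannel(img, "AF"))
  expect_error(subtractAutofluorescence(img, "nope", c(ch2 = 1)),
               "unknown autofluorescence channel")
  expect_error(subtractAutofluorescence(img, "AF", c(chX = 1)),
               "unknown channel")
})

test_that("spillover matrices survive a CSV round trip bit-exactly", {
  M <- testSpillover(off = 1 / 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpilloverCSV(M, path)
  back <- readSpilloverCSV(path)
  expect_identical(spilloverCoefficients(back), spilloverCoefficients(M))
})
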