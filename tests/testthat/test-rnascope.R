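# RNAscope punctum detection, classification and vRNA reporting.

rnascopeFixture <- function() cached("rnascopeFixture", function() {
  scn <- referenceScene("rnascope_reference", seed = 3)
  runPipeline(scn, "rnascope_panel")
})

test_that("a blank vRNA channel yields an empty SpotSet", {
  img <- multichannelImage(array(0, c(60, 60, 1)), "vRNA", 1)
  spots <- detectSpots(img, "vRNA")
  expect_identical(nrow(spotData(spots)), 0L)
})

test_that("puncta are recovered within 10% and doubling intensity moves nothing", {
  fx <- rnascopeFixture()
  gt <- fx$scene
  truth <- rbind(gt@cellPuncta[, c("y_um", "x_um")],
                 gt@fdcPuncta[, c("y_um", "x_um")])
  sp <- spotData(fx$spots)
  expect_lt(abs(nrow(sp) - nrow(truth)) / nrow(truth), 0.1)
  # match detections to truth within ~1 punctum radius
  rad <- gt@config$vrna$punctum_radius_um
  D <- outer(sp$y_um, truth$y_um, "-")^2 + outer(sp$x_um, truth$x_um, "-")^2
  expect_gte(mean(sqrt(apply(D, 1, min)) <= 1.5 * rad), 0.9)
  # scale robustness: doubled amplitudes, same centroids
  img2 <- fx$image
  idx <- HistoCyto:::.channelIndex(img2, "vRNA")
  img2@data[, , idx] <- img2@data[, , idx] * 2
  sp2 <- spotData(detectSpots(img2, "vRNA"))
  common <- min(nrow(sp), nrow(sp2))
  expect_gte(common / nrow(sp), 0.95)
  D12 <- outer(sp$y_um, sp2$y_um, "-")^2 + outer(sp$x_um, sp2$x_um, "-")^2
  expect_true(all(sqrt(apply(D12[seq_len(nrow(sp)), , drop = FALSE], 1,
                             min)) <= 1))
})

test_that("classification respects the cell > FDC > unassigned precedence", {
  lab <- matrix(0L, 50, 50)
  lab[HistoCyto:::diskIndices(50, 50, 12, 12, 4)] <- 1L
  labels <- new("LabelMap", labels = lab, pixelSize = 1)
  fdc <- matrix(FALSE, 50, 50)
  fdc[30:40, 30:40] <- TRUE
  fdc[10:14, 10:14] <- TRUE                # overlaps the cell: cell wins
  spots <- new("SpotSet", spots = data.frame(
    spot_id = 1:3,
    y_um = c(11.5, 35, 45), x_um = c(11.5, 35, 5),
    radius_um = 0.8, intensity = 50,
    assignment = "unassigned", stringsAsFactors = FALSE), pixelSize = 1)
  out <- spotData(classifySpots(spots, labels, fdc))
  expect_identical(out$assignment, c("1", "fdc_bound", "unassigned"))
})

test_that("generator FDC-bound puncta classify as FDC-bound, cell puncta as cells", {
  fx <- rnascopeFixture()
  gt <- fx$scene
  sp <- spotData(fx$spots)
  # match each detected spot to the nearest true FDC-bound punctum
  fp <- gt@fdcPuncta
  D <- outer(sp$y_um, fp$y_um, "-")^2 + outer(sp$x_um, fp$x_um, "-")^2
  isTrueFdc <- sqrt(apply(D, 1, min)) <= 1.5
  expect_gte(mean(sp$assignment[isTrueFdc] == "fdc_bound"), 0.9)
  # conservation: every spot has exactly one assignment class
  cls <- HistoCyto:::.assignmentClass(sp$assignment)
  expect_identical(sum(cls == "cell") + sum(cls == "fdc_bound") +
                     sum(cls == "unassigned"), nrow(sp))
})

test_that("the vRNA report has sane structure and conserves counts", {
  fx <- rnascopeFixture()
  rep <- fx$vrna
  expect_true(all(rep$cell_rates$pct_vrna_pos >= 0 &
                    rep$cell_rates$pct_vrna_pos <= 100, na.rm = TRUE))
  expect_true(all(rep$fdc_bound$fdc_bound_count >= 0))
  sp <- spotData(fx$spots)
  expect_lte(sum(rep$fdc_bound$fdc_bound_count),
             sum(sp$assignment == "fdc_bound"))
  # per-follicle FDC-bound burdens within 10% of the generator counts
  truthCounts <- table(factor(fx$scene@fdcPuncta$follicle_id,
                              levels = rep$fdc_bound$follicle_id))
  meas <- rep$fdc_bound$fdc_bound_count
  expect_lte(sum(abs(meas - as.integer(truthCounts))),
             ceiling(0.1 * sum(truthCounts)) + 1)
})

test_that("no spots means all cells vRNA negative", {
  fx <- rnascopeFixture()
  empty <- new("SpotSet", spots = spotData(fx$spots)[0, ],
               pixelSize = 1)
  rep <- reportVrna(empty, fx$cells, fx$map)
  expect_true(all(rep$cell_rates$vrna_pos == 0))
  expect_true(all(rep$fdc_bound$fdc_bound_count == 0))
})

test_that("configured per-phenotype vRNA rates are recovered (binomial bounds)", {
  fx <- rnascopeFixture()
  rates <- fx$vrna$cell_rates
  efDim <- rates[rates$population == "CD4dim" & rates$scope == "EF", ]
  trueRate <- fx$scene@config$vrna$cell_assoc_rate$EF$T4dim
  expect_gte(efDim$n, 100)
  se <- sqrt(trueRate * (1 - trueRate) / efDim$n)
  expect_lt(abs(efDim$pct_vrna_pos / 100 - trueRate), 3 * se + 0.02)
})
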