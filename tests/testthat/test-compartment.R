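# Compartment mapping, cell assignment and structural areas.

test_that("a blank follicle marker yields an all-EF map with a warning", {
  arr <- array(0, c(80, 80, 2))
  arr[, , 2] <- 5
  img <- multichannelImage(arr, c("CD20", "Ki67"), 1)
  expect_warning(map <- buildCompartmentMap(img, list(cd20 = "CD20",
                                                      ki67 = "Ki67")),
                 "all EF")
  expect_true(all(regionData(map) == regionCodes()[["EF"]]))
  expect_true(all(follicleData(map) == 0L))
})

test_that("a missing marker key is a configuration error", {
  img <- multichannelImage(array(0, c(10, 10, 1)), "CD20", 1)
  expect_error(buildCompartmentMap(img, list(cd20 = "CD20")), "ki67")
})

test_that("configured follicles are recovered as distinct instances", {
  cfg <- follicleSceneConfig(field = 1300, seed = 31, n_follicles = 3)
  gt <- buildScene(cfg)
  optics <- defaultOptics(follicleChannels())
  img <- compensate(renderScene(gt, optics), optics$spillover)
  map <- buildCompartmentMap(img, list(cd20 = "CD20", ki67 = "Ki67"),
                             follicle_erosion_um = 0, gc_erosion_um = 0)
  expect_identical(max(follicleData(map)), 3L)
  codes <- regionCodes()
  for (f in 1:3) {
    inF <- follicleData(map) == f
    expect_gt(sum(inF & regionData(map) == codes[["MZ"]]), 0)
    expect_gt(sum(inF & regionData(map) %in% codes[c("LZ", "DZ")]), 0)
  }
  tm <- trueCompartmentMap(gt)
  expect_gte(jaccard(regionData(map) > 1, regionData(tm) > 1), 0.8)
})

test_that("region codes partition the field; GC = LZ + DZ within follicles", {
  fx <- follicleFixture()
  rc <- regionData(map <- fx$map)
  codes <- regionCodes()
  expect_true(all(rc %in% codes))
  expect_identical(sum(vapply(codes, function(cd) sum(rc == cd), numeric(1))),
                   as.numeric(length(rc)))
  lz <- rc == codes[["LZ"]]; dz <- rc == codes[["DZ"]]
  expect_identical(sum(lz & dz), 0L)
  fid <- follicleData(map)
  expect_true(all(fid[lz | dz] > 0))
  expect_true(all(fid[rc == codes[["EF"]]] == 0))
})

test_that("cells are assigned the compartment of their centroid pixel", {
  fx <- follicleFixture()
  cc <- cellData(fx$cells)
  expect_true(all(cc$region %in% names(regionCodes())))
  expect_identical(anyNA(cc$region), FALSE)
  # agreement with the generator's compartment at a coarse EF/MZ/GC level
  idx <- matchTruth(fx$cells, fx$gt)
  truth <- groundTruthCells(fx$gt)$compartment[idx]
  coarse <- function(x) ifelse(x %in% c("LZ", "DZ"), "GC", x)
  expect_gte(mean(coarse(cc$region) == coarse(truth)), 0.9)
  # empty table passes through
  empty <- new("CellTable",
               cells = cellData(fx$cells)[0, 1:5])
  expect_identical(nrow(cellData(assignCompartments(empty, fx$map))), 0L)
})

test_that("structural areas satisfy the partition arithmetic", {
  fx <- cached("structureFixture", function() {
    scn <- referenceScene("structure_reference", seed = 2)
    runPipeline(scn, "structure_panel", stages = list(areas = TRUE))
  })
  a <- fx$areas
  expect_true(all(abs(a$follicles$follicle_um2 -
                        (a$follicles$mz_um2 + a$follicles$gc_um2)) < 1e-6))
  expect_true(all(a$field$collagen_hi_um2 >= 0, na.rm = TRUE))
  expect_lte(max(a$field$collagen_hi_um2, na.rm = TRUE),
             a$total_tissue_area_um2)
  # FDC-dense staining is confined to germinal centres
  fdc <- HistoCyto:::.fdcHiMask(fx$image, "FDC")
  tgc <- regionData(trueCompartmentMap(fx$scene)) %in%
    regionCodes()[c("LZ", "DZ")]
  expect_lte(sum(fdc & !tgc) / sum(fdc), 0.02)
})

test_that("blank structural channels yield zero areas", {
  fx <- follicleFixture()
  img <- fx$img
  blank <- array(0, dim(img@data)[1:2])
  img@data <- array(c(img@data, blank), c(dim(blank), nChannels(img) + 1))
  img@channelNames <- c(channelNames(fx$img), "Collagen")
  a <- quantifyAreas(fx$map, img, list(collagen = "Collagen"))
  expect_true(all(a$field$collagen_hi_um2 == 0))
  expect_error(quantifyAreas(fx$map, img, list(bogus = "Collagen")),
               "unknown structural marker")
})

test_that("halving the FDC mesh density halves its relative area", {
  area1 <- cached("fdcArea1", function() {
    cfg <- follicleSceneConfig(field = 700, seed = 41, fdc = 0.16)
    gt <- buildScene(cfg)
    optics <- defaultOptics(follicleChannels(fdc = 1))
    img <- renderScene(gt, optics)
    a <- quantifyAreas(trueCompartmentMap(gt), img, list(fdc = "FDC"))
    sum(a$follicles$fdc_hi_um2) / sum(a$follicles$follicle_um2)
  })
  area2 <- cached("fdcArea2", function() {
    cfg <- follicleSceneConfig(field = 700, seed = 41, fdc = 0.08)
    gt <- buildScene(cfg)
    optics <- defaultOptics(follicleChannels(fdc = 1))
    img <- renderScene(gt, optics)
    a <- quantifyAreas(trueCompartmentMap(gt), img, list(fdc = "FDC"))
    sum(a$follicles$fdc_hi_um2) / sum(a$follicles$follicle_um2)
  })
  expect_lt(abs(area2 / area1 - 0.5) / 0.5, 0.2)
})
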