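# Scene generator: validation, determinism, composition recovery.

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sceneConfig(
    field_size_um = c(200, 200), n_follicles = 0,
    composition = list(EF = c(B = 0.5, T = 0.6)),
    markers = "CD20", marker_localization = c(CD20 = "membrane"),
    phenotype_profiles = list(B = list(), T = list()), seed = 1),
    "sums to")
  expect_error(sceneConfig(
    field_size_um = c(200, 200), n_follicles = 2,
    follicle_axes_um = c(150, 160),
    composition = list(EF = c(other = 1)),
    markers = character(0), marker_localization = character(0),
    phenotype_profiles = list(other = list()), seed = 1) |> buildScene(),
    "follicle 1")
  expect_error(sceneConfig(
    field_size_um = c(300, 300), n_follicles = 0,
    composition = list(EF = c(B = 1)),
    markers = "CD20", marker_localization = c(CD20 = "membrane"),
    phenotype_profiles = list(B = list(CD19 = c(100, 0.3))), seed = 1),
    "absent from the panel")
})

test_that("a follicle-free configuration yields an EF-only scene", {
  gt <- buildScene(flatSceneConfig(field = 300, density = 1000))
  tc <- groundTruthCells(gt)
  expect_gt(nrow(tc), 50)
  expect_true(all(tc$compartment == "EF"))
  expect_identical(nrow(gt@follicles), 0L)
})

test_that("scene generation is deterministic in the seed", {
  cfg <- flatSceneConfig(field = 300, density = 1000, seed = 5)
  a <- buildScene(cfg)
  b <- buildScene(cfg)
  expect_identical(groundTruthCells(a), groundTruthCells(b))
  cfg2 <- flatSceneConfig(field = 300, density = 1000, seed = 6)
  c <- buildScene(cfg2)
  expect_false(isTRUE(all.equal(groundTruthCells(a)$y_um,
                                groundTruthCells(c)$y_um)))
})

test_that("phenotype fractions recover the configured composition", {
  cfg <- flatSceneConfig(field = 1000, density = 2500, seed = 3,
                         bFrac = 0.3, tFrac = 0.5)
  tc <- groundTruthCells(buildScene(cfg))
  n <- nrow(tc)
  expect_gte(n, 2000)
  for (ph in c("B", "T", "other")) {
    p <- cfg$composition$EF[[ph]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(tc$phenotype == ph) - p), 3 * se + 1e-9)
  }
})

test_that("germinal-centre composition matches the configured GC fractions", {
  # GC composition structured like the reference study population mix
  comp <- c(B = 0.83, CD4 = 0.06, Tfh = 0.04, Tfr = 0.0003, other = 0.0697)
  cfg <- sceneConfig(
    field_size_um = c(900, 900), n_follicles = 2,
    follicle_axes_um = c(170, 195), gc_fraction = 0.6,
    composition = list(EF = c(other = 1), MZ = c(B = 1),
                       LZ = comp, DZ = comp),
    cell_density_mm2 = c(EF = 1500, MZ = 3000, LZ = 7000, DZ = 7000),
    markers = "CD20", marker_localization = c(CD20 = "membrane"),
    phenotype_profiles = list(B = list(CD20 = c(600, 0.3)), CD4 = list(),
                              Tfh = list(), Tfr = list(), other = list()),
    seed = 9)
  tc <- groundTruthCells(buildScene(cfg))
  gc <- tc[tc$compartment %in% c("LZ", "DZ"), ]
  expect_gt(nrow(gc), 600)
  for (ph in c("B", "CD4", "Tfh")) {
    p <- comp[[ph]]
    se <- sqrt(p * (1 - p) / nrow(gc))
    expect_lt(abs(mean(gc$phenotype == ph) - p), 3 * se + 1e-9)
  }
})

test_that("every cell lies in exactly one compartment, consistent with the geometry", {
  fx <- follicleFixture()
  tc <- groundTruthCells(fx$gt)
  expect_true(all(tc$compartment %in% c("EF", "MZ", "LZ", "DZ")))
  tm <- trueCompartmentMap(fx$gt)
  codes <- regionCodes()
  px <- pixelSize(tm)
  iy <- pmin(nrow(regionData(tm)), floor(tc$y_um / px) + 1)
  ix <- pmin(ncol(regionData(tm)), floor(tc$x_um / px) + 1)
  atCell <- regionData(tm)[cbind(iy, ix)]
  expect_true(all(atCell == codes[tc$compartment]))
})

test_that("nuclei honour the minimum-spacing rule", {
  cfg <- flatSceneConfig(field = 400, density = 3000, seed = 2)
  tc <- groundTruthCells(buildScene(cfg))
  d <- as.matrix(dist(tc[, c("y_um", "x_um")]))
  diag(d) <- Inf
  lim <- outer(tc$nucleus_radius_um, tc$nucleus_radius_um, "+") *
    cfg$min_spacing_factor
  expect_true(all(d >= lim - 1e-9))
})
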