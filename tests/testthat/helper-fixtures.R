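# Shared test fixtures, built lazily and memoised for the session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# Simple extrafollicular-only scene: three phenotypes on two markers.
flatSceneConfig <- function(field = 500, density = 2000, seed = 11,
                            bFrac = 0.3, tFrac = 0.5) {
  sceneConfig(
    field_size_um = c(field, field), n_follicles = 0,
    composition = list(EF = c(B = bFrac, T = tFrac,
                              other = 1 - bFrac - tFrac)),
    cell_density_mm2 = c(EF = density, MZ = 0, LZ = 0, DZ = 0),
    markers = c("CD20", "CD4"),
    marker_localization = c(CD20 = "membrane", CD4 = "membrane"),
    phenotype_profiles = list(
      B = list(CD20 = c(600, 0.3)),
      T = list(CD4 = c(500, 0.3)),
      other = list()),
    seed = seed)
}

testSpillover <- function(channels = c("DNA", "CD20", "CD4"),
                          off = 0.15) {
  m <- diag(length(channels))
  dimnames(m) <- list(channels, channels)
  m[1, 2] <- off
  m[2, 3] <- off / 2
  spilloverMatrix(m)
}

identitySpillover <- function(channels = c("DNA", "CD20", "CD4")) {
  m <- diag(length(channels))
  dimnames(m) <- list(channels, channels)
  spilloverMatrix(m)
}

quietOptics <- function(channels = c("DNA", "CD20", "CD4"),
                        spill = identitySpillover(channels),
                        af = 0, gaussian = 0, poisson = 0) {
  opticsConfig(spill, psf_sigma_um = 0.6, autofluorescence = af,
               noise = list(gaussian_sd = gaussian, poisson_scale = poisson))
}

defaultOptics <- function(channels = c("DNA", "CD20", "CD4"),
                          spill = identitySpillover(channels)) {
  opticsConfig(spill, psf_sigma_um = 0.6, autofluorescence = 3,
               noise = list(gaussian_sd = 1.5, poisson_scale = 0.5))
}

# A two-follicle scene with the CD20/Ki67/CD4 backbone (mini version of
# the reference composition structure).
follicleSceneConfig <- function(field = 900, seed = 21, n_follicles = 2,
                                axes = NULL, fdc = 0) {
  if (is.null(axes)) {
    # keep follicles inside their placement slots regardless of field size
    slot <- field / ceiling(n_follicles / max(1, round(sqrt(n_follicles))))
    axes <- round(c(0.30, 0.36) * slot)
  }
  sceneConfig(
    field_size_um = c(field, field), n_follicles = n_follicles,
    follicle_axes_um = axes, gc_fraction = 0.5, dz_fraction = 0.4,
    composition = list(
      EF = c(B_EF = 0.06, T = 0.45, other = 0.49),
      MZ = c(B_MZ = 0.8, T = 0.15, other = 0.05),
      LZ = c(B_LZ = 0.83, T = 0.06, other = 0.11),
      DZ = c(B_DZ = 0.83, T = 0.06, other = 0.11)),
    markers = c("CD20", "Ki67", "CD4", if (fdc > 0) "FDC"),
    marker_localization = c(CD20 = "membrane", Ki67 = "nuclear",
                            CD4 = "membrane",
                            if (fdc > 0) c(FDC = "membrane")),
    phenotype_profiles = list(
      B_EF = list(CD20 = c(600, 0.3)),
      B_MZ = list(CD20 = c(220, 0.3)),
      B_LZ = list(CD20 = c(600, 0.3), Ki67 = c(120, 0.6)),
      B_DZ = list(CD20 = c(220, 0.3), Ki67 = c(550, 0.3)),
      T = list(CD4 = c(500, 0.3)),
      other = list()),
    fdc_density = fdc,
    seed = seed)
}

follicleChannels <- function(fdc = 0)
  c("DNA", "CD20", "Ki67", "CD4", if (fdc > 0) "FDC")

# Cached mid-size follicle scene rendered under realistic optics.
follicleFixture <- function() cached("follicleFixture", function() {
  cfg <- follicleSceneConfig()
  gt <- buildScene(cfg)
  optics <- defaultOptics(follicleChannels())
  img <- compensate(renderScene(gt, optics), optics$spillover)
  labels <- segmentNuclei(img, "DNA")
  cells <- extractFeatures(labels, img)
  map <- suppressWarnings(buildCompartmentMap(
    img, list(cd20 = "CD20", ki67 = "Ki67", cd4 = "CD4")))
  cells <- assignCompartments(cells, map)
  list(cfg = cfg, gt = gt, optics = optics, img = img, labels = labels,
       cells = cells, map = map)
})

# Match segmented cells to the nearest ground-truth cell; returns the
# ground-truth row index per cell.
matchTruth <- function(cells, gt) {
  cc <- cellData(cells)
  tc <- groundTruthCells(gt)
  idx <- integer(nrow(cc))
  for (s in seq(1, nrow(cc), 1000)) {
    e <- min(s + 999, nrow(cc))
    D <- outer(cc$y_um[s:e], tc$y_um, "-")^2 +
      outer(cc$x_um[s:e], tc$x_um, "-")^2
    idx[s:e] <- apply(D, 1, which.min)
  }
  idx
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Minimal gate tree over the backbone panel.
backboneTree <- function() gateTree("backbone", list(
  all = list(parent = ""),
  B = list(parent = "all", channels = c(CD20 = "hi/dim", CD4 = "-")),
  CD4T = list(parent = "all", channels = c(CD4 = "+", CD20 = "lo"))))

backboneThresholdSpec <- function() list(
  CD20 = list(method = "cluster", levels = 2),
  Ki67 = list(method = "background", levels = 2, k = 4.5),
  CD4 = list(method = "kde", levels = 2))
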