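# Synthetic lymphoid-tissue scene generation.
#
# A scene is a field of nucleated cells partitioned into microanatomical
# compartments: elliptical B-cell follicles containing a germinal centre
# (GC, split into a Ki67-dense dark zone and a light zone) surrounded by a
# mantle zone, embedded in extrafollicular space. Each cell carries a
# phenotype drawn from the configured per-compartment composition and a true
# marker-expression vector drawn from its phenotype profile.

#' Scene configuration for the synthetic tissue generator
#'
#' Assembles and validates the full parameterisation of a synthetic
#' lymphoid-tissue scene. Compositions are per-compartment phenotype
#' fraction maps and must each sum to 1; all phenotype-profile markers must
#' be members of \code{markers}.
#'
#' @param field_size_um field height and width in micrometres.
#' @param pixel_size_um micrometres per pixel of the rendered image.
#' @param n_follicles number of follicles to place.
#' @param follicle_axes_um range (min, max) of the follicle semi-major axis.
#' @param axis_ratio_range range of the minor/major axis ratio.
#' @param gc_fraction fraction of each follicle's area occupied by its GC.
#' @param dz_fraction fraction of each GC's area occupied by the dark zone.
#' @param composition named list (\code{EF}, \code{MZ}, \code{LZ},
#'   \code{DZ}), each a named numeric vector of phenotype fractions summing
#'   to 1.
#' @param cell_density_mm2 named numeric, cells per mm^2 per compartment.
#' @param markers panel marker names (excluding the nuclear stain).
#' @param marker_localization named character, \code{"nuclear"} or
#'   \code{"membrane"} per marker.
#' @param phenotype_profiles named list: phenotype -> named list of
#'   \code{c(mean, cv)} expression levels per marker (markers omitted from a
#'   profile are not expressed).
#' @param nuclear_channel name of the nuclear stain channel.
#' @param nuclear_intensity \code{c(mean, cv)} of the nuclear stain level.
#' @param nucleus_radius_um \code{c(mean, sd)} of nucleus radii.
#' @param min_spacing_factor minimum centre spacing between nuclei as a
#'   multiple of the summed radii of the pair.
#' @param membrane_width_um width of the membrane/cytoplasmic annulus used
#'   when rendering surface markers.
#' @param fdc_density target coverage fraction of the FDC meshwork within
#'   each GC (0 disables the mesh).
#' @param fdc_intensity rendered intensity of the FDC mesh (on the marker
#'   named \code{"FDC"}, when present in \code{markers}).
#' @param structural_channels named list of diffuse structural stains:
#'   each entry \code{list(compartments, coverage, amplitude)} is rendered
#'   as a smoothed-noise texture mask confined to the named compartments.
#' @param vrna \code{NULL}, or a list with \code{channel},
#'   \code{cell_assoc_rate} (compartment -> phenotype -> probability of
#'   being vRNA+), \code{puncta_per_cell} (mean extra puncta beyond the
#'   first, Poisson), \code{fdc_bound_count} (per follicle; recycled),
#'   \code{punctum_radius_um} and \code{punctum_intensity}.
#' @param seed integer seed controlling all scene randomness.
#' @return a validated scene-configuration list of class \code{"SceneConfig"}.
#' @seealso \code{\link{buildScene}}, \code{\link{renderScene}}
#' @export
sceneConfig <- function(field_size_um = c(900, 900),
                        pixel_size_um = 1,
                        n_follicles = 2,
                        follicle_axes_um = c(150, 190),
                        axis_ratio_range = c(0.82, 0.95),
                        gc_fraction = 0.5,
                        dz_fraction = 0.4,
                        composition,
                        cell_density_mm2 = c(EF = 2500, MZ = 4000,
                                             LZ = 4000, DZ = 4000),
                        markers,
                        marker_localization,
                        phenotype_profiles,
                        nuclear_channel = "DNA",
                        nuclear_intensity = c(180, 0.12),
                        nucleus_radius_um = c(3, 0.35),
                        min_spacing_factor = 0.8,
                        membrane_width_um = 1.2,
                        fdc_density = 0,
                        fdc_intensity = 400,
                        structural_channels = list(),
                        vrna = NULL,
                        seed = 1L) {
  cfg <- list(
    field_size_um = as.numeric(field_size_um),
    pixel_size_um = as.numeric(pixel_size_um),
    n_follicles = as.integer(n_follicles),
    follicle_axes_um = as.numeric(follicle_axes_um),
    axis_ratio_range = as.numeric(axis_ratio_range),
    gc_fraction = as.numeric(gc_fraction),
    dz_fraction = as.numeric(dz_fraction),
    composition = lapply(composition, function(x) unlist(x)),
    cell_density_mm2 = unlist(cell_density_mm2),
    markers = as.character(markers),
    marker_localization = unlist(marker_localization),
    phenotype_profiles = phenotype_profiles,
    nuclear_channel = nuclear_channel,
    nuclear_intensity = as.numeric(nuclear_intensity),
    nucleus_radius_um = as.numeric(nucleus_radius_um),
    min_spacing_factor = as.numeric(min_spacing_factor),
    membrane_width_um = as.numeric(membrane_width_um),
    fdc_density = as.numeric(fdc_density),
    fdc_intensity = as.numeric(fdc_intensity),
    structural_channels = structural_channels,
    vrna = vrna,
    seed = as.integer(seed)
  )
  class(cfg) <- "SceneConfig"
  validateSceneConfig(cfg)
  cfg
}

#' Validate a scene configuration
#'
#' Checks composition sums, fraction ranges, positivity constraints and
#' marker consistency; stops with an informative message on the first
#' violation.
#'
#' @param cfg a \code{"SceneConfig"} list.
#' @return the configuration, invisibly.
#' @export
validateSceneConfig <- function(cfg) {
  stopifnot(length(cfg$field_size_um) == 2)
  if (any(cfg$field_size_um <= 0) || cfg$pixel_size_um <= 0)
    stop("field size and pixel size must be strictly positive", call. = FALSE)
  for (comp in names(cfg$composition)) {
    fr <- cfg$composition[[comp]]
    if (abs(sum(fr) - 1) > 1e-9)
      stop(sprintf("composition for compartment '%s' sums to %.10f, not 1",
                   comp, sum(fr)), call. = FALSE)
    if (any(fr < 0 | fr > 1))
      stop(sprintf("composition fractions for '%s' must lie in [0,1]", comp),
           call. = FALSE)
  }
  fracs <- c(gc = cfg$gc_fraction, dz = cfg$dz_fraction, fdc = cfg$fdc_density)
  if (any(fracs < 0 | fracs > 1))
    stop("gc_fraction, dz_fraction and fdc_density must lie in [0,1]",
         call. = FALSE)
  if (any(cfg$cell_density_mm2 < 0))
    stop("cell densities must be non-negative", call. = FALSE)
  if (cfg$nucleus_radius_um[1] <= 0)
    stop("mean nucleus radius must be strictly positive", call. = FALSE)
  if (cfg$n_follicles > 0 && any(cfg$follicle_axes_um <= 0))
    stop("follicle axes must be strictly positive", call. = FALSE)
  profMarkers <- unique(unlist(lapply(cfg$phenotype_profiles, names)))
  unknown <- setdiff(profMarkers, cfg$markers)
  if (length(unknown))
    stop("phenotype profiles reference markers absent from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  badComp <- setdiff(names(cfg$composition), c("EF", "MZ", "LZ", "DZ"))
  if (length(badComp))
    stop("unknown compartment(s) in composition: ",
         paste(badComp, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Build the ground truth of a synthetic scene
#'
#' Places follicles, partitions the field into EF/MZ/LZ/DZ, draws the FDC
#' meshwork, places nuclei by minimum-spacing (Poisson-disk style) sampling
#' at the configured per-compartment densities, draws each cell's phenotype
#' from the compartment composition (multinomial) and its true expression
#' vector from the phenotype profile, and places RNAscope puncta. Fully
#' deterministic for a fixed \code{cfg$seed}.
#'
#' @param cfg a validated \code{\link{sceneConfig}}.
#' @return a \linkS4class{SceneGroundTruth}.
#' @examples
#' cfg <- sceneConfig(
#'   field_size_um = c(300, 300), n_follicles = 0,
#'   composition = list(EF = c(B = 0.3, T = 0.7)),
#'   cell_density_mm2 = c(EF = 1500, MZ = 0, LZ = 0, DZ = 0),
#'   markers = c("CD20", "CD4"),
#'   marker_localization = c(CD20 = "membrane", CD4 = "membrane"),
#'   phenotype_profiles = list(
#'     B = list(CD20 = c(600, 0.3)),
#'     T = list(CD4 = c(500, 0.3))),
#'   seed = 7)
#' scene <- buildScene(cfg)
#' nrow(groundTruthCells(scene))
#' @export
buildScene <- function(cfg) {
  validateSceneConfig(cfg)
  withSeed(cfg$seed, .buildSceneImpl(cfg))
}

.buildSceneImpl <- function(cfg) {
  px <- cfg$pixel_size_um
  H <- round(cfg$field_size_um[1] / px)
  W <- round(cfg$field_size_um[2] / px)

  follicles <- .placeFollicles(cfg, H, W)
  geo <- .rasterizeRegions(follicles, H, W, px, cfg)
  regionImg <- geo$regionImg
  follicleImg <- geo$follicleImg
  follicles <- geo$follicles

  fdcMask <- matrix(FALSE, H, W)
  if (cfg$fdc_density > 0 && nrow(follicles) > 0)
    fdcMask <- .drawFdcMesh(follicles, regionImg, follicleImg, H, W, px, cfg)

  cells <- .placeCells(cfg, regionImg, follicleImg, H, W, px)
  cells <- .drawExpression(cfg, cells)

  pun <- .placePuncta(cfg, cells, follicles, fdcMask, follicleImg, H, W, px)
  cells$vrna_puncta <- pun$perCell

  new("SceneGroundTruth", cells = cells, follicles = follicles,
      fdcMask = fdcMask, fdcPuncta = pun$fdcPuncta,
      cellPuncta = pun$cellPuncta, config = unclass(cfg))
}

# Grid-with-jitter placement keeps follicles disjoint and clear of the field
# border; fails loudly (naming the follicle) when the field cannot host the
# requested geometry.
.placeFollicles <- function(cfg, H, W) {
  px <- cfg$pixel_size_um
  n <- cfg$n_follicles
  empty <- data.frame(id = integer(0), cy_um = numeric(0), cx_um = numeric(0),
                      a_um = numeric(0), b_um = numeric(0), theta = numeric(0),
                      gc_scale = numeric(0), dz_uy = numeric(0),
                      dz_ux = numeric(0), dz_cut = numeric(0))
  if (n == 0) return(empty)
  Hum <- H * px; Wum <- W * px
  nr <- max(1L, round(sqrt(n * Hum / Wum)))
  nc <- ceiling(n / nr)
  while (nr * nc < n) nc <- nc + 1L
  cellH <- Hum / nr; cellW <- Wum / nc
  # clearance per grid slot; adjacent follicles stay >= 2*margin apart
  margin <- 25
  out <- empty
  for (i in seq_len(n)) {
    a <- runif(1, cfg$follicle_axes_um[1], cfg$follicle_axes_um[2])
    b <- a * runif(1, cfg$axis_ratio_range[1], cfg$axis_ratio_range[2])
    if (2 * a + 2 * margin > min(cellH, cellW))
      stop(sprintf(paste("field too small to place follicle %d:",
                         "semi-major axis %.0f um does not fit a %.0f x %.0f um slot"),
                   i, a, cellH, cellW), call. = FALSE)
    r <- (i - 1) %/% nc; cc <- (i - 1) %% nc
    jit <- pmax(0, c(cellH, cellW) / 2 - a - margin)
    cy <- (r + 0.5) * cellH + runif(1, -jit[1], jit[1])
    cx <- (cc + 0.5) * cellW + runif(1, -jit[2], jit[2])
    theta <- runif(1, 0, pi)
    pole <- runif(1, 0, 2 * pi)
    out <- rbind(out, data.frame(
      id = i, cy_um = cy, cx_um = cx, a_um = a, b_um = b, theta = theta,
      gc_scale = sqrt(cfg$gc_fraction), dz_uy = sin(pole), dz_ux = cos(pole),
      dz_cut = NA_real_))
  }
  out
}

# Rasterise follicle geometry into region-code and follicle-id images and
# resolve the dark-zone cut (a chord through the GC perpendicular to the
# polarity axis, placed so the DZ holds `dz_fraction` of the GC area).
# The resolved dz_cut is returned with the follicle table.
.rasterizeRegions <- function(follicles, H, W, px, cfg) {
  codes <- regionCodes()
  regionImg <- matrix(codes[["EF"]], H, W)
  follicleImg <- matrix(0L, H, W)
  if (nrow(follicles) == 0)
    return(list(regionImg = regionImg, follicleImg = follicleImg,
                follicles = follicles))
  for (i in seq_len(nrow(follicles))) {
    f <- follicles[i, ]
    y0 <- max(1, floor((f$cy_um - f$a_um) / px)); y1 <- min(H, ceiling((f$cy_um + f$a_um) / px))
    x0 <- max(1, floor((f$cx_um - f$a_um) / px)); x1 <- min(W, ceiling((f$cx_um + f$a_um) / px))
    ys <- y0:y1; xs <- x0:x1
    dy <- (ys - 0.5) * px - f$cy_um
    dx <- (xs - 0.5) * px - f$cx_um
    DY <- matrix(dy, length(ys), length(xs))
    DX <- matrix(dx, length(ys), length(xs), byrow = TRUE)
    u <- (DX * cos(f$theta) + DY * sin(f$theta)) / f$a_um
    v <- (-DX * sin(f$theta) + DY * cos(f$theta)) / f$b_um
    e <- u^2 + v^2
    inF <- e <= 1
    inGC <- e <= f$gc_scale^2
    reg <- regionImg[ys, xs]; fid <- follicleImg[ys, xs]
    reg[inF] <- codes[["MZ"]]
    fid[inF] <- f$id
    if (any(inGC)) {
      proj <- (DX * f$dz_ux + DY * f$dz_uy)[inGC]
      cut <- as.numeric(quantile(proj, 1 - cfg$dz_fraction, names = FALSE))
      follicles$dz_cut[i] <- cut
      gcReg <- ifelse((DX * f$dz_ux + DY * f$dz_uy) > cut,
                      codes[["DZ"]], codes[["LZ"]])
      reg[inGC] <- gcReg[inGC]
    }
    regionImg[ys, xs] <- reg
    follicleImg[ys, xs] <- fid
  }
  list(regionImg = regionImg, follicleImg = follicleImg, follicles = follicles)
}

# Random dendritic skeleton: correlated random walks seeded inside the GC,
# marked onto the pixel grid and lightly thickened, repeated until the
# requested GC coverage fraction is reached.
.drawFdcMesh <- function(follicles, regionImg, follicleImg, H, W, px, cfg) {
  codes <- regionCodes()
  mask <- matrix(FALSE, H, W)
  gcCode <- c(codes[["LZ"]], codes[["DZ"]])
  for (i in seq_len(nrow(follicles))) {
    f <- follicles[i, ]
    inGC <- follicleImg == f$id & matrix(regionImg %in% gcCode, H, W)
    gcIdx <- which(inGC)
    if (!length(gcIdx)) next
    # the 1 px skeleton is thickened ~3x below; aim the skeleton
    # coverage so the final mesh hits the configured fraction
    target <- cfg$fdc_density * length(gcIdx) / 3
    local <- matrix(FALSE, H, W)
    covered <- 0L
    guard <- 0L
    while (covered < target && guard < 4000L) {
      guard <- guard + 1L
      start <- gcIdx[sample.int(length(gcIdx), 1)]
      y <- ((start - 1) %% H) + 1; x <- ((start - 1) %/% H) + 1
      ang <- runif(1, 0, 2 * pi)
      for (s in seq_len(400)) {
        y <- y + 0.8 * sin(ang); x <- x + 0.8 * cos(ang)
        ang <- ang + rnorm(1, 0, 0.45)
        yi <- round(y); xi <- round(x)
        if (yi < 1 || yi > H || xi < 1 || xi > W || !inGC[yi, xi]) break
        if (!local[yi, xi]) {
          local[yi, xi] <- TRUE
          covered <- covered + 1L
          if (covered >= target) break
        }
      }
    }
    mask <- mask | local
  }
  # thicken to ~2 px so the mesh survives PSF blurring
  thick <- EBImage::dilate(EBImage::Image(mask * 1),
                           EBImage::makeBrush(3, shape = "box"))
  (matrix(as.numeric(thick), H, W) > 0) & .regionIn(regionImg, c("LZ", "DZ"))
}

.regionIn <- function(regionImg, names) {
  codes <- regionCodes()
  matrix(regionImg %in% unname(codes[names]), nrow(regionImg), ncol(regionImg))
}

# Minimum-spacing placement at per-compartment density; phenotypes are a
# multinomial draw from the compartment composition. The spacing rule is
# per pair: centres must be at least min_spacing_factor * (r_i + r_j)
# apart, so large nuclei keep proportionally larger clearances.
.placeCells <- function(cfg, regionImg, follicleImg, H, W, px) {
  codes <- regionCodes()
  rMean <- cfg$nucleus_radius_um[1] / px
  rSd <- cfg$nucleus_radius_um[2] / px
  rMaxPair <- 2 * (rMean + 3 * rSd) * cfg$min_spacing_factor
  gcell <- max(rMaxPair / 2, 1e-6)
  gx <- ceiling(W / gcell); gy <- ceiling(H / gcell)
  occY <- rep(NA_real_, gy * gx); occX <- rep(NA_real_, gy * gx)
  occR <- rep(NA_real_, gy * gx)
  allY <- numeric(0); allX <- numeric(0); allR <- numeric(0)
  compLab <- character(0); phenoLab <- character(0); folId <- integer(0)

  for (comp in c("EF", "MZ", "LZ", "DZ")) {
    dens <- cfg$cell_density_mm2[[comp]] %||% 0
    if (is.na(dens) || dens <= 0) next
    compFrac <- cfg$composition[[comp]]
    if (is.null(compFrac)) next
    idx <- which(regionImg == codes[[comp]])
    if (!length(idx)) next
    areaMm2 <- length(idx) * px^2 / 1e6
    nC <- round(dens * areaMm2)
    if (nC == 0) next
    placedY <- numeric(nC); placedX <- numeric(nC); placedF <- integer(nC)
    placedR <- numeric(nC)
    k <- 0L; tries <- 0L; maxTries <- nC * 60L
    while (k < nC && tries < maxTries) {
      tries <- tries + 1L
      pix <- idx[sample.int(length(idx), 1)]
      yy <- ((pix - 1) %% H) + runif(1)
      xx <- ((pix - 1) %/% H) + runif(1)
      rr <- max(1.6 / px, rnorm(1, rMean, rSd))
      gi <- floor(yy / gcell); gj <- floor(xx / gcell)
      ok <- TRUE
      for (di in -2:2) {
        ii <- gi + di
        if (ii < 0 || ii >= gy) next
        for (dj in -2:2) {
          jj <- gj + dj
          if (jj < 0 || jj >= gx) next
          q <- ii * gx + jj + 1
          if (!is.na(occY[q])) {
            lim <- cfg$min_spacing_factor * (rr + occR[q])
            if ((occY[q] - yy)^2 + (occX[q] - xx)^2 < lim^2) {
              ok <- FALSE; break
            }
          }
        }
        if (!ok) break
      }
      if (ok) {
        k <- k + 1L
        placedY[k] <- yy; placedX[k] <- xx; placedR[k] <- rr
        placedF[k] <- follicleImg[pix]
        q <- gi * gx + gj + 1
        occY[q] <- yy; occX[q] <- xx; occR[q] <- rr
      }
    }
    if (k < nC)
      stop(sprintf("could not place %d cells in compartment %s (placed %d); reduce density or spacing",
                   nC, comp, k), call. = FALSE)
    cnt <- as.integer(rmultinom(1, nC, compFrac))
    ph <- sample(rep(names(compFrac), cnt))
    allY <- c(allY, placedY); allX <- c(allX, placedX)
    allR <- c(allR, placedR)
    compLab <- c(compLab, rep(comp, nC))
    phenoLab <- c(phenoLab, ph)
    folId <- c(folId, placedF)
  }
  n <- length(allY)
  data.frame(
    id = seq_len(n),
    y_um = allY * px, x_um = allX * px,
    nucleus_radius_um = allR * px,
    phenotype = phenoLab,
    compartment = compLab,
    follicle_id = folId,
    vrna_puncta = integer(n),
    stringsAsFactors = FALSE
  )
}

.drawExpression <- function(cfg, cells) {
  n <- nrow(cells)
  ni <- cfg$nuclear_intensity
  cells$nuclear_intensity <- if (n) rlnormMeanCV(n, ni[1], ni[2]) else numeric(0)
  for (m in cfg$markers) {
    v <- numeric(n)
    for (ph in unique(cells$phenotype)) {
      sel <- which(cells$phenotype == ph)
      prof <- cfg$phenotype_profiles[[ph]][[m]]
      if (!is.null(prof) && prof[1] > 0)
        v[sel] <- rlnormMeanCV(length(sel), prof[1], prof[2])
    }
    cells[[paste0("expr_", m)]] <- v
  }
  cells
}

# RNAscope puncta: cell-associated puncta in a cytoplasmic shell around
# vRNA+ cells; FDC-bound puncta on mesh pixels kept clear of nuclei so the
# ground-truth assignment is unambiguous.
.placePuncta <- function(cfg, cells, follicles, fdcMask, follicleImg, H, W, px) {
  emptyF <- data.frame(y_um = numeric(0), x_um = numeric(0),
                       follicle_id = integer(0))
  emptyC <- data.frame(y_um = numeric(0), x_um = numeric(0),
                       cell_id = integer(0))
  perCell <- integer(nrow(cells))
  if (is.null(cfg$vrna))
    return(list(perCell = perCell, fdcPuncta = emptyF, cellPuncta = emptyC))
  v <- cfg$vrna
  rates <- numeric(nrow(cells))
  for (comp in names(v$cell_assoc_rate)) {
    rc <- unlist(v$cell_assoc_rate[[comp]])
    for (ph in names(rc)) {
      sel <- cells$compartment == comp & cells$phenotype == ph
      rates[sel] <- rc[[ph]]
    }
  }
  pos <- runif(nrow(cells)) < rates
  perCell[pos] <- 1L + rpois(sum(pos), v$puncta_per_cell %||% 0.8)
  minSep <- 3  # keep sibling puncta separable at the optical resolution
  cp <- emptyC
  for (i in which(pos)) {
    k <- perCell[i]
    ys <- numeric(0); xs <- numeric(0)
    for (j in seq_len(k)) {
      for (try in 1:25) {
        d <- runif(1, 0.4, cells$nucleus_radius_um[i] + 1.2)
        a <- runif(1, 0, 2 * pi)
        yy <- cells$y_um[i] + d * sin(a); xx <- cells$x_um[i] + d * cos(a)
        if (!length(ys) || min((ys - yy)^2 + (xs - xx)^2) >= minSep^2) {
          ys <- c(ys, yy); xs <- c(xs, xx); break
        }
      }
    }
    perCell[i] <- length(ys)
    if (length(ys))
      cp <- rbind(cp, data.frame(y_um = ys, x_um = xs,
                                 cell_id = cells$id[i]))
  }
  fp <- emptyF
  nF <- nrow(follicles)
  if (nF > 0 && !is.null(v$fdc_bound_count) && any(v$fdc_bound_count > 0)) {
    counts <- rep(v$fdc_bound_count, length.out = nF)
    meshIdx <- which(fdcMask)
    if (length(meshIdx)) {
      meshY <- ((meshIdx - 1) %% H) + 0.5
      meshX <- ((meshIdx - 1) %/% H) + 0.5
      meshF <- follicleImg[meshIdx]
      guard <- (cfg$nucleus_radius_um[1] + 2.5) / px
      for (i in seq_len(nF)) {
        cand <- which(meshF == follicles$id[i])
        if (!length(cand)) next
        cy <- cells$y_um / px; cx <- cells$x_um / px
        placed <- 0L; tries <- 0L
        py <- numeric(0); pxs <- numeric(0)
        while (placed < counts[i] && tries < counts[i] * 200L) {
          tries <- tries + 1L
          j <- cand[sample.int(length(cand), 1)]
          if (length(cy)) {
            d2 <- (cy - meshY[j])^2 + (cx - meshX[j])^2
            if (min(d2) < guard^2) next
          }
          if (length(py) &&
              min((py - meshY[j])^2 + (pxs - meshX[j])^2) < (3 / px)^2)
            next
          py <- c(py, meshY[j]); pxs <- c(pxs, meshX[j])
          fp <- rbind(fp, data.frame(y_um = meshY[j] * px, x_um = meshX[j] * px,
                                     follicle_id = follicles$id[i]))
          placed <- placed + 1L
        }
        if (placed < counts[i])
          warning(sprintf("follicle %d: placed %d/%d FDC-bound puncta clear of nuclei",
                          follicles$id[i], placed, counts[i]))
      }
    } else warning("fdc_bound_count requested but the scene has no FDC mesh")
  }
  list(perCell = perCell, fdcPuncta = fp, cellPuncta = cp)
}

#' Ground-truth compartment map of a scene
#'
#' Recomputes the exact region-code and follicle-id images implied by the
#' scene's follicle geometry (no imaging, no noise). This is the oracle
#' against which \code{\link{buildCompartmentMap}} is validated.
#'
#' @param scene a \linkS4class{SceneGroundTruth}.
#' @return a \linkS4class{CompartmentMap}.
#' @export
trueCompartmentMap <- function(scene) {
  cfg <- scene@config
  px <- cfg$pixel_size_um
  H <- round(cfg$field_size_um[1] / px)
  W <- round(cfg$field_size_um[2] / px)
  geo <- .rasterizeRegions(scene@follicles, H, W, px, cfg)
  new("CompartmentMap", regionCodes = geo$regionImg,
      follicleIds = geo$follicleImg, pixelSize = px)
}
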