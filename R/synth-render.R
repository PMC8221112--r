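# Rendering of scenes into multichannel images through a simple optics
# model: per-pixel spectral mixing (spillover), additive autofluorescence,
# Gaussian PSF blur, Poisson-Gaussian noise and bit-depth clipping.

#' Optics configuration for rendering
#'
#' @param spillover a \linkS4class{SpilloverMatrix}; its row/column names fix
#'   the channel order of the rendered image.
#' @param psf_sigma_um Gaussian point-spread sigma in micrometres (> 0).
#' @param autofluorescence scalar or per-channel named vector of additive
#'   background levels (>= 0).
#' @param noise list with \code{gaussian_sd} (additive read noise sd) and
#'   \code{poisson_scale} (photon gain s: counts are drawn as
#'   \code{rpois(s * signal) / s}; \code{0} disables shot noise).
#' @param bit_depth integer bit depth; intensities are clipped to
#'   \code{[0, 2^bit_depth - 1]}.
#' @return an \code{"OpticsConfig"} list.
#' @export
opticsConfig <- function(spillover,
                         psf_sigma_um = 0.6,
                         autofluorescence = 3,
                         noise = list(gaussian_sd = 1.5, poisson_scale = 0.5),
                         bit_depth = 16L) {
  stopifnot(is(spillover, "SpilloverMatrix"))
  channels <- rownames(spilloverCoefficients(spillover))
  if (length(autofluorescence) == 1L && is.null(names(autofluorescence)))
    autofluorescence <- setNames(rep(autofluorescence, length(channels)),
                                 channels)
  if (psf_sigma_um <= 0) stop("psf_sigma_um must be > 0", call. = FALSE)
  if (any(autofluorescence < 0))
    stop("autofluorescence levels must be >= 0", call. = FALSE)
  out <- list(spillover = spillover, channels = channels,
              psf_sigma_um = psf_sigma_um,
              autofluorescence = autofluorescence,
              noise = noise, bit_depth = as.integer(bit_depth))
  class(out) <- "OpticsConfig"
  out
}

#' Render a scene into a multichannel image
#'
#' The nuclear stain is drawn over each nucleus disk; nuclear-localised
#' markers over the same disk; membrane/cytoplasmic markers over an annulus
#' of the configured width around the nucleus. The FDC meshwork, diffuse
#' structural stains and RNAscope puncta (Gaussian spots) are added to their
#' channels, spillover is applied per pixel as \code{observed = t(M) true},
#' autofluorescence is added, the image is PSF-blurred, then Poisson-Gaussian
#' noise is applied and values are clipped to the bit depth.
#'
#' @param scene a \linkS4class{SceneGroundTruth}.
#' @param optics an \code{\link{opticsConfig}}.
#' @param seed seed for the noise draws; defaults to a render-specific
#'   derivation of the scene seed, so (scene, optics) renders are
#'   reproducible.
#' @param zSlices number of z-slices; 1 (default) renders a single plane,
#'   3-5 render a thin stack (the in-focus plane plus progressively
#'   defocused copies) for exercising maximum-intensity projection.
#' @return a \linkS4class{MultichannelImage}.
#' @export
renderScene <- function(scene, optics,
                        seed = deriveSeed(scene@config$seed, "render"),
                        zSlices = 1L) {
  withSeed(seed, .renderImpl(scene, optics, zSlices))
}

.renderImpl <- function(scene, optics, zSlices = 1L) {
  cfg <- scene@config
  px <- cfg$pixel_size_um
  H <- round(cfg$field_size_um[1] / px)
  W <- round(cfg$field_size_um[2] / px)
  channels <- optics$channels
  needed <- c(cfg$nuclear_channel, cfg$markers,
              if (!is.null(cfg$vrna)) cfg$vrna$channel,
              names(cfg$structural_channels))
  missing <- setdiff(needed, channels)
  if (length(missing))
    stop("scene channels absent from the optics channel list: ",
         paste(missing, collapse = ", "), call. = FALSE)

  true <- array(0, c(H, W, length(channels)))
  dimnames(true) <- list(NULL, NULL, channels)
  chIdx <- setNames(seq_along(channels), channels)

  cells <- scene@cells
  exprMat <- as.matrix(cells[, paste0("expr_", cfg$markers), drop = FALSE])
  nucIdx <- chIdx[[cfg$nuclear_channel]]
  memW <- cfg$membrane_width_um
  planeSize <- H * W
  n <- nrow(cells)
  disks <- vector("list", n); annuli <- vector("list", n)
  nucOcc <- matrix(FALSE, H, W)
  for (i in seq_len(n)) {
    cy <- cells$y_um[i] / px; cx <- cells$x_um[i] / px
    r <- cells$nucleus_radius_um[i] / px
    disks[[i]] <- diskIndices(H, W, cy, cx, r)
    annuli[[i]] <- diskIndices(H, W, cy, cx, r + memW / px, rInner = r)
    nucOcc[disks[[i]]] <- TRUE
  }
  # volume exclusion: a neighbour's nucleus displaces most of this cell's
  # membrane/cytoplasm along z, so annulus signal over foreign nuclei is
  # attenuated rather than painted at full strength
  nucShade <- 0.1
  for (i in seq_len(n)) {
    disk <- disks[[i]]; ann <- annuli[[i]]
    annW <- ifelse(nucOcc[ann], nucShade, 1)
    true[disk + (nucIdx - 1L) * planeSize] <-
      true[disk + (nucIdx - 1L) * planeSize] + cells$nuclear_intensity[i]
    for (j in seq_along(cfg$markers)) {
      e <- exprMat[i, j]
      if (e <= 0) next
      m <- cfg$markers[j]
      off <- (chIdx[[m]] - 1L) * planeSize
      if (identical(cfg$marker_localization[[m]], "nuclear")) {
        true[disk + off] <- true[disk + off] + e
      } else {
        true[ann + off] <- true[ann + off] + e * annW
      }
    }
  }

  if ("FDC" %in% cfg$markers && any(scene@fdcMask)) {
    off <- (chIdx[["FDC"]] - 1L) * planeSize
    idx <- which(scene@fdcMask)
    true[idx + off] <- true[idx + off] + cfg$fdc_intensity
  }

  if (length(cfg$structural_channels)) {
    regions <- trueCompartmentMap(scene)
    for (nm in names(cfg$structural_channels)) {
      sc <- cfg$structural_channels[[nm]]
      tex <- .structuralTexture(regions, sc, px)
      off <- (chIdx[[nm]] - 1L) * planeSize
      idx <- which(tex)
      true[idx + off] <- true[idx + off] + sc$amplitude
    }
  }

  if (!is.null(cfg$vrna)) {
    off <- (chIdx[[cfg$vrna$channel]] - 1L) * planeSize
    pts <- rbind(scene@cellPuncta[, c("y_um", "x_um")],
                 scene@fdcPuncta[, c("y_um", "x_um")])
    sg <- cfg$vrna$punctum_radius_um / px
    amp <- cfg$vrna$punctum_intensity
    if (nrow(pts)) for (i in seq_len(nrow(pts))) {
      cy <- pts$y_um[i] / px; cx <- pts$x_um[i] / px
      w <- ceiling(3 * sg)
      ys <- max(1, round(cy) - w):min(H, round(cy) + w)
      xs <- max(1, round(cx) - w):min(W, round(cx) + w)
      d2 <- outer((ys - 0.5 - cy)^2, (xs - 0.5 - cx)^2, "+")
      patch <- amp * exp(-d2 / (2 * sg^2))
      lin <- rep((xs - 1) * H, each = length(ys)) + ys + off
      true[lin] <- true[lin] + as.numeric(patch)
    }
  }

  .applyOptics(true, optics, px, zSlices)
}

# Mixing -> autofluorescence -> PSF -> noise -> clip. For thin z-stacks the
# in-focus plane is re-blurred at increasing sigma to emulate defocus.
.applyOptics <- function(true, optics, px, zSlices = 1L) {
  d <- dim(true); H <- d[1]; W <- d[2]
  channels <- optics$channels
  M <- spilloverCoefficients(optics$spillover)
  mixed <- unflattenChannels(flattenChannels(true) %*% M, H, W)
  af <- optics$autofluorescence[channels]
  noiseOne <- function(plane, ch) {
    x <- plane + af[[ch]]
    x <- gaussianBlur(x, optics$psf_sigma_um, px)
    s <- optics$noise$poisson_scale %||% 0
    if (s > 0) x <- matrix(rpois(length(x), pmax(x, 0) * s) / s, nrow(x))
    gsd <- optics$noise$gaussian_sd %||% 0
    if (gsd > 0) x <- x + rnorm(length(x), 0, gsd)
    pmin(pmax(x, 0), 2^optics$bit_depth - 1)
  }
  if (zSlices <= 1L) {
    out <- array(0, c(H, W, length(channels)))
    for (k in seq_along(channels))
      out[, , k] <- noiseOne(mixed[, , k], channels[k])
    return(multichannelImage(out, channels, px,
                             metadata = list(compensated = FALSE)))
  }
  out <- array(0, c(H, W, zSlices, length(channels)))
  mid <- (zSlices + 1) / 2
  for (k in seq_along(channels)) for (z in seq_len(zSlices)) {
    defocus <- abs(z - mid) * optics$psf_sigma_um
    plane <- if (defocus > 0)
      gaussianBlur(mixed[, , k], defocus, px) * (1 / (1 + defocus)) else
      mixed[, , k]
    out[, , z, k] <- noiseOne(plane, channels[k])
  }
  multichannelImage(out, channels, px, zStep = 1,
                    metadata = list(compensated = FALSE))
}

# Smoothed-noise texture confined to named compartments, hitting a target
# coverage fraction of those compartments.
.structuralTexture <- function(map, sc, px) {
  allowed <- .regionIn(regionData(map), sc$compartments)
  if (!any(allowed) || sc$coverage <= 0)
    return(matrix(FALSE, nrow(allowed), ncol(allowed)))
  noise <- matrix(runif(length(allowed)), nrow(allowed))
  sm <- gaussianBlur(noise, sc$smooth_um %||% 12, px)
  cut <- quantile(sm[allowed], 1 - sc$coverage, names = FALSE)
  (sm > cut) & allowed
}

#' Render single-stain control images
#'
#' For each fluorophore of the panel, renders the scene with only that
#' fluorophore's source active (its marker, the nuclear stain, the FDC mesh,
#' a structural stain or the RNAscope channel, as appropriate) under the
#' exact same optics -- including spillover, autofluorescence and noise -- as
#' the full panel. These controls drive \code{\link{estimateSpillover}}.
#'
#' @inheritParams renderScene
#' @return named list of \linkS4class{MultichannelImage}, one per channel.
#' @export
renderSingleStains <- function(scene, optics,
                               seed = deriveSeed(scene@config$seed, "singles")) {
  cfg <- scene@config
  out <- list()
  for (f in optics$channels) {
    sub <- scene
    subCfg <- cfg
    if (!identical(f, cfg$nuclear_channel))
      sub@cells$nuclear_intensity <- rep(0, nrow(sub@cells))
    for (m in cfg$markers)
      if (!identical(m, f))
        sub@cells[[paste0("expr_", m)]] <- rep(0, nrow(sub@cells))
    if (!identical(f, "FDC")) sub@fdcMask <- sub@fdcMask & FALSE
    subCfg$structural_channels <- cfg$structural_channels[
      intersect(names(cfg$structural_channels), f)]
    if (!is.null(cfg$vrna) && !identical(f, cfg$vrna$channel))
      subCfg$vrna <- NULL
    sub@config <- subCfg
    out[[f]] <- renderScene(sub, optics, seed = deriveSeed(seed, f))
  }
  out
}
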