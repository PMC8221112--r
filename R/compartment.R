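# Microanatomical compartment mapping from CD20/Ki67 staining density,
# cell-to-compartment assignment and structural area quantification.

# Lower boundary of a 3-class lo/dim/hi split of a staining-density
# field. Class centres are iterated medians (robust to the skewed
# within-region density distribution); the cut is the midpoint of the lo
# and dim centres, which places the mask boundary at the half-height of
# the smoothed density step. Returns +Inf when the field lacks contrast
# (blank-channel guard), so the thresholded mask is empty.
.clusterLowerCut <- function(x, contrastRatio = 1.5) {
  if (length(x) > 2e5) x <- x[seq(1L, length(x), length.out = 2e5)]
  ctr <- quantile(x, c(0.15, 0.55, 0.92), names = FALSE)
  if (diff(range(ctr)) < 1e-9) return(Inf)
  for (i in 1:25) {
    b1 <- (ctr[1] + ctr[2]) / 2; b2 <- (ctr[2] + ctr[3]) / 2
    upd <- c(median(x[x <= b1]), median(x[x > b1 & x <= b2]),
             median(x[x > b2]))
    if (any(!is.finite(upd))) break
    done <- max(abs(upd - ctr)) < 1e-6
    ctr <- upd
    if (done) break
  }
  if (ctr[3] < contrastRatio * ctr[1] + 1e-6) return(Inf)
  (ctr[1] + ctr[2]) / 2
}

#' Build a compartment map from marker channels
#'
#' Follicles are the connected components (above \code{min_follicle_area})
#' of the density-smoothed, thresholded CD20 channel. Within each follicle,
#' the smoothed-Ki67-dense region (after a morphological opening) is the
#' germinal centre; the dark zone is the largest connected region above a
#' second, higher Ki67 density threshold inside the GC, the light zone is
#' the remainder of the GC and the mantle zone is the follicle outside the
#' GC. Everything else is extrafollicular. When a CD4 channel is supplied,
#' a T-cell-zone mask (CD4-dense extrafollicular space) is derived as well.
#'
#' @param image a compensated single-plane \linkS4class{MultichannelImage}.
#' @param markers named list/character: \code{cd20} and \code{ki67} channel
#'   names, optionally \code{cd4} for the T-cell-zone mask. \code{cd20}
#'   may name several channels; their smoothed densities are summed (e.g.
#'   CD3 + CD4 for panels that delineate follicles as T-marker-low areas).
#' @param density_sigma_um staining-density smoothing sigma.
#' @param cd20_threshold \code{"cluster"} (lower boundary of a 3-class
#'   lo/dim/hi density split; the default), \code{"otsu"}, or a fixed cut
#'   on the smoothed CD20.
#' @param ki67_threshold \code{"cluster"}, \code{"otsu"} (computed over
#'   follicle pixels) or a fixed cut for the GC; the DZ sub-threshold is
#'   always Otsu over GC pixels (bimodal LZ/DZ density).
#' @param min_follicle_area_um2 smallest accepted follicle.
#' @param gc_opening_um radius of the morphological opening of the GC mask.
#' @param follicle_erosion_um border clearance: the follicle mask is eroded
#'   by this much (the band reverts to EF), biasing follicular scopes
#'   toward well-defined interior tissue.
#' @param gc_erosion_um border clearance of the GC mask (the band reverts
#'   to MZ).
#' @param cd4_quantile quantile of the smoothed CD4 density over EF pixels
#'   above which EF space counts as T-cell zone.
#' @param invert_follicle_marker when TRUE follicles are taken as the
#'   regions of \emph{low} marker density, below the lo/dim class boundary
#'   (e.g. the RNAscope panel, where B-cell follicles are the
#'   CD3-low/CD4-low areas).
#' @return a \linkS4class{CompartmentMap}.
#' @export
buildCompartmentMap <- function(image, markers,
                                density_sigma_um = 16,
                                cd20_threshold = "cluster",
                                ki67_threshold = "cluster",
                                min_follicle_area_um2 = 3e4,
                                gc_opening_um = 6,
                                follicle_erosion_um = 8,
                                gc_erosion_um = 20,
                                cd4_quantile = 0.4,
                                invert_follicle_marker = FALSE) {
  for (need in c("cd20", "ki67"))
    if (is.null(markers[[need]]))
      stop("markers must name a '", need, "' channel", call. = FALSE)
  px <- pixelSize(image)
  codes <- regionCodes()
  cd20 <- Reduce(`+`, lapply(markers[["cd20"]], function(ch)
    gaussianBlur(getChannel(image, ch), density_sigma_um, px)))
  ki67 <- gaussianBlur(getChannel(image, markers[["ki67"]]),
                       density_sigma_um, px)
  cut20 <- if (identical(cd20_threshold, "cluster")) .clusterLowerCut(cd20)
    else if (identical(cd20_threshold, "otsu")) otsuThreshold(cd20)
    else as.numeric(cd20_threshold)
  # inverted semantics: follicles are the low-density class (panels whose
  # follicle landmark is the absence of T-cell markers)
  fmask <- if (invert_follicle_marker) cd20 < cut20 else cd20 > cut20
  H <- nrow(fmask); W <- ncol(fmask)
  region <- matrix(codes[["EF"]], H, W)
  fids <- matrix(0L, H, W)
  if (any(fmask)) {
    fmask <- EBImage::fillHull(EBImage::Image(fmask * 1)) > 0
    fmask <- .erodeMask(fmask, follicle_erosion_um, px)
    lab <- EBImage::bwlabel(EBImage::Image(fmask * 1))
    lab <- matrix(as.integer(lab), H)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * px^2 >= min_follicle_area_um2)
    if (length(keep)) {
      remap <- integer(length(sizes)); remap[keep] <- seq_along(keep)
      pos <- lab > 0L
      lab[pos] <- remap[lab[pos]]
      fids <- lab
      region[fids > 0L] <- codes[["MZ"]]
      inF <- fids > 0L
      cutK <- if (identical(ki67_threshold, "cluster"))
        .clusterLowerCut(ki67[inF])
      else if (identical(ki67_threshold, "otsu")) otsuThreshold(ki67[inF])
      else as.numeric(ki67_threshold)
      gc <- inF & (ki67 > cutK)
      if (any(gc) && gc_opening_um > 0) {
        brush <- EBImage::makeBrush(
          max(3L, 2L * as.integer(gc_opening_um / px / 2) + 1L), "disc")
        gc <- matrix(as.numeric(EBImage::opening(EBImage::Image(gc * 1),
                                                 brush)), H) > 0
        gc <- gc & inF
      }
      if (any(gc)) {
        gc <- EBImage::fillHull(EBImage::Image(gc * 1)) > 0 & inF
        gc <- .erodeMask(gc, gc_erosion_um, px)
      }
      if (any(gc)) {
        region[gc] <- codes[["LZ"]]
        cutDZ <- otsuThreshold(ki67[gc])
        dzCand <- gc & (ki67 > cutDZ)
        if (any(dzCand)) {
          # per follicle keep the largest connected Ki67-dense region
          dzLab <- matrix(as.integer(EBImage::bwlabel(
            EBImage::Image(dzCand * 1))), H)
          for (f in seq_along(keep)) {
            comp <- unique(dzLab[dzLab > 0L & fids == f])
            if (!length(comp)) next
            szs <- vapply(comp, function(k) sum(dzLab == k & fids == f),
                          integer(1))
            best <- comp[which.max(szs)]
            region[dzLab == best & fids == f] <- codes[["DZ"]]
          }
        }
      }
    } else warning("no follicles above the minimum area; map is all EF")
  } else warning("blank CD20 density; map is all EF")

  tz <- matrix(FALSE, H, W)
  if (!is.null(markers[["cd4"]])) {
    cd4 <- gaussianBlur(getChannel(image, markers[["cd4"]]),
                        density_sigma_um, px)
    ef <- region == codes[["EF"]]
    if (any(ef)) {
      cutT <- quantile(cd4[ef], cd4_quantile, names = FALSE)
      tz <- ef & (cd4 > cutT)
    }
  }
  out <- new("CompartmentMap", regionCodes = region, follicleIds = fids,
             pixelSize = px)
  attr(out@regionCodes, "tzone") <- NULL
  out@follicleIds <- fids
  out <- .setTzone(out, tz)
  out
}

# Erode a binary mask by a metric radius (no-op for radius 0).
.erodeMask <- function(mask, radius_um, px) {
  if (radius_um <= 0 || !any(mask)) return(mask)
  k <- 2L * as.integer(radius_um / px) + 1L
  if (k < 3L) return(mask)
  out <- EBImage::erode(EBImage::Image(mask * 1), EBImage::makeBrush(k, "disc"))
  matrix(as.numeric(out), nrow(mask)) > 0
}

# The T-cell-zone mask rides along as an attribute so the class contract
# (one region code per pixel) stays intact.
.setTzone <- function(map, tz) { attr(map@follicleIds, "tzone") <- tz; map }

#' T-cell-zone mask of a compartment map
#'
#' @param map a \linkS4class{CompartmentMap} built with a \code{cd4} marker.
#' @return logical matrix (all-FALSE when no CD4 channel was supplied).
#' @export
tzoneMask <- function(map) {
  tz <- attr(map@follicleIds, "tzone")
  if (is.null(tz)) matrix(FALSE, nrow(map@regionCodes), ncol(map@regionCodes))
  else tz
}

#' Assign cells to compartments
#'
#' Each cell receives the region code, follicle id and T-zone flag of the
#' pixel containing its centroid.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param map a \linkS4class{CompartmentMap} on the same micrometre frame.
#' @return the \linkS4class{CellTable} with \code{region},
#'   \code{follicle_id} and \code{tzone} columns (input ordering preserved).
#' @export
assignCompartments <- function(cells, map) {
  cc <- cellData(cells)
  px <- pixelSize(map)
  H <- nrow(regionData(map)); W <- ncol(regionData(map))
  if (nrow(cc)) {
    iy <- pmin(H, pmax(1L, as.integer(floor(cc$y_um / px)) + 1L))
    ix <- pmin(W, pmax(1L, as.integer(floor(cc$x_um / px)) + 1L))
    if (any(cc$y_um / px > H + 0.5 | cc$x_um / px > W + 0.5))
      stop("cell centroids fall outside the compartment map frame",
           call. = FALSE)
    lin <- (ix - 1L) * H + iy
    codes <- regionCodes()
    cc$region <- names(codes)[match(regionData(map)[lin], codes)]
    cc$follicle_id <- follicleData(map)[lin]
    cc$tzone <- tzoneMask(map)[lin]
  } else {
    cc$region <- character(0); cc$follicle_id <- integer(0)
    cc$tzone <- logical(0)
  }
  out <- cells
  out@cells <- cc
  out
}

#' Quantify structural areas
#'
#' Per-follicle areas of the follicle, MZ and GC and of the FDC-dense mesh
#' inside the follicle, plus field-level areas of collagen-dense and
#' CD31-dense-within-collagen-dense staining stratified by EF / follicle /
#' GC, and the total tissue area (nuclear staining density above a
#' presence threshold).
#'
#' @param map a \linkS4class{CompartmentMap}.
#' @param image the matching \linkS4class{MultichannelImage}.
#' @param structuralMarkers named list: any of \code{fdc}, \code{collagen},
#'   \code{cd31}, \code{igd} channel names, plus \code{nuclear} for the
#'   tissue-presence channel.
#' @param thresholds named list of fixed cuts per structural marker;
#'   missing entries default to Otsu on the smoothed channel.
#' @param smooth_um smoothing applied before thresholding structural
#'   channels.
#' @return list with \code{follicles} (data.frame of per-follicle areas,
#'   um^2), \code{field} (data.frame of structural areas by EF/F/GC) and
#'   \code{total_tissue_area_um2}.
#' @export
quantifyAreas <- function(map, image, structuralMarkers = list(),
                          thresholds = list(), smooth_um = 3) {
  known <- c("fdc", "collagen", "cd31", "igd", "nuclear")
  unknown <- setdiff(names(structuralMarkers), known)
  if (length(unknown))
    stop("unknown structural marker key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  px <- pixelSize(map)
  pxa <- px^2
  codes <- regionCodes()
  region <- regionData(map)
  fids <- follicleData(map)
  gcMask <- region == codes[["LZ"]] | region == codes[["DZ"]]
  fMask <- gcMask | region == codes[["MZ"]]
  efMask <- !fMask

  hiMask <- function(key) {
    ch <- structuralMarkers[[key]]
    if (is.null(ch)) return(NULL)
    sm <- gaussianBlur(getChannel(image, ch), smooth_um, px)
    cut <- thresholds[[key]] %||% otsuThreshold(sm)
    if (max(sm) <= min(sm) + 1e-9) return(sm > Inf)  # blank channel
    sm > cut
  }
  fdcHi <- hiMask("fdc"); colHi <- hiMask("collagen"); cd31Hi <- hiMask("cd31")

  nF <- max(fids)
  fol <- data.frame(follicle_id = seq_len(nF),
                    follicle_um2 = NA_real_, mz_um2 = NA_real_,
                    gc_um2 = NA_real_, fdc_hi_um2 = NA_real_)
  for (f in seq_len(nF)) {
    inF <- fids == f
    fol$follicle_um2[f] <- sum(inF) * pxa
    fol$gc_um2[f] <- sum(inF & gcMask) * pxa
    fol$mz_um2[f] <- sum(inF & !gcMask) * pxa
    fol$fdc_hi_um2[f] <- if (is.null(fdcHi)) NA_real_ else
      sum(inF & fdcHi) * pxa
  }

  field <- data.frame(scope = c("EF", "F", "GC"),
                      collagen_hi_um2 = NA_real_,
                      cd31_collagen_hi_um2 = NA_real_,
                      fdc_hi_um2 = NA_real_)
  scopes <- list(EF = efMask, F = fMask, GC = gcMask)
  for (i in seq_along(scopes)) {
    m <- scopes[[i]]
    if (!is.null(colHi)) field$collagen_hi_um2[i] <- sum(m & colHi) * pxa
    if (!is.null(colHi) && !is.null(cd31Hi))
      field$cd31_collagen_hi_um2[i] <- sum(m & colHi & cd31Hi) * pxa
    if (!is.null(fdcHi)) field$fdc_hi_um2[i] <- sum(m & fdcHi) * pxa
  }

  total <- NA_real_
  if (!is.null(structuralMarkers$nuclear)) {
    dens <- gaussianBlur(getChannel(image, structuralMarkers$nuclear),
                         8, px)
    # presence, not segmentation: any appreciable nuclear density counts
    cut <- thresholds$nuclear %||% (0.25 * mean(dens))
    total <- sum(dens > cut) * pxa
  }
  list(follicles = fol, field = field, total_tissue_area_um2 = total)
}
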