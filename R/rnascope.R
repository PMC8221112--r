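# RNAscope punctum detection (scale-normalised Laplacian-of-Gaussian blob
# detection), cell-associated vs FDC-bound classification, and vRNA
# reporting.

#' Detect RNAscope puncta
#'
#' Difference-of-Gaussian approximation of the scale-normalised Laplacian
#' over a range of scales; local maxima of the scale-space response above
#' \code{threshold} are kept, then greedily non-maximum suppressed at
#' \code{min_separation_um}. Spot radius is estimated as sqrt(2) times the
#' best-responding sigma. All spots start unassigned.
#'
#' @param image a compensated single-plane \linkS4class{MultichannelImage}.
#' @param vrnaChannel name of the vRNA channel.
#' @param log_sigma_range_um range of blob scales (sigma, micrometres).
#' @param threshold minimum blob response (intensity units).
#' @param min_separation_um minimum distance between accepted spots.
#' @param n_scales number of scales spanning the range.
#' @return a \linkS4class{SpotSet}.
#' @export
detectSpots <- function(image, vrnaChannel,
                        log_sigma_range_um = c(0.5, 1.2),
                        threshold = 20,
                        min_separation_um = 1.8,
                        n_scales = 3L) {
  px <- pixelSize(image)
  plane <- getChannel(image, vrnaChannel)
  H <- nrow(plane); W <- ncol(plane)
  emptySpots <- data.frame(spot_id = integer(0), y_um = numeric(0),
                           x_um = numeric(0), radius_um = numeric(0),
                           intensity = numeric(0),
                           assignment = character(0))
  if (max(plane) - min(plane) < 1e-9)
    return(new("SpotSet", spots = emptySpots, pixelSize = px))
  sigmas <- seq(log_sigma_range_um[1], log_sigma_range_um[2],
                length.out = n_scales)
  kratio <- 1.6
  best <- matrix(-Inf, H, W)
  bestSigma <- matrix(sigmas[1], H, W)
  for (sg in sigmas) {
    g1 <- gaussianBlur(plane, sg, px)
    g2 <- gaussianBlur(plane, sg * kratio, px)
    # scale-normalised DoG response (positive for bright blobs)
    resp <- (g1 - g2) * kratio / (kratio - 1)
    upd <- resp > best
    best[upd] <- resp[upd]
    bestSigma[upd] <- sg
  }
  mx <- EBImage::dilate(EBImage::Image(best),
                        EBImage::makeBrush(3, shape = "box"))
  isPeak <- (best >= matrix(as.numeric(mx), H)) & (best > threshold)
  idx <- which(isPeak)
  if (!length(idx))
    return(new("SpotSet", spots = emptySpots, pixelSize = px))
  yy <- ((idx - 1) %% H) + 1; xx <- ((idx - 1) %/% H) + 1
  resp <- best[idx]
  ord <- order(resp, decreasing = TRUE)
  yy <- yy[ord]; xx <- xx[ord]; resp <- resp[ord]; idx <- idx[ord]
  minSepPx <- min_separation_um / px
  keep <- logical(length(idx))
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_along(idx)) {
    if (length(ky) && min((ky - yy[i])^2 + (kx - xx[i])^2) < minSepPx^2)
      next
    keep[i] <- TRUE
    ky <- c(ky, yy[i]); kx <- c(kx, xx[i])
  }
  yy <- yy[keep]; xx <- xx[keep]; resp <- resp[keep]; idx <- idx[keep]
  spots <- data.frame(
    spot_id = seq_along(idx),
    y_um = (yy - 0.5) * px, x_um = (xx - 0.5) * px,
    radius_um = sqrt(2) * bestSigma[idx],
    intensity = resp,
    assignment = "unassigned",
    stringsAsFactors = FALSE)
  new("SpotSet", spots = spots, pixelSize = px)
}

#' Classify puncta as cell-associated or FDC-bound
#'
#' A spot is assigned to a cell when its centroid falls within that cell's
#' nuclear label dilated by \code{cell_radius_expand_um} (a cytoplasmic rim
#' around the segmented nucleus); otherwise it is FDC-bound when it falls
#' on the FDC-dense mask; otherwise unassigned. Cells take precedence over
#' the FDC mesh.
#'
#' @param spots a \linkS4class{SpotSet}.
#' @param labels the \linkS4class{LabelMap} from nuclear segmentation.
#' @param fdcMask logical matrix of FDC-dense pixels on the same grid.
#' @param cell_radius_expand_um cytoplasmic expansion of the nuclear label.
#' @return the \linkS4class{SpotSet} with assignments filled in.
#' @export
classifySpots <- function(spots, labels, fdcMask,
                          cell_radius_expand_um = 1.5) {
  sp <- spotData(spots)
  lab <- labelData(labels)
  px <- pixelSize(labels)
  if (abs(px - spots@pixelSize) > 1e-9)
    stop("spot set and label map are on different pixel grids", call. = FALSE)
  if (!identical(dim(lab), dim(fdcMask)))
    stop("FDC mask and label map shapes differ", call. = FALSE)
  if (!nrow(sp)) return(spots)
  expanded <- expandLabels(labels, cell_radius_expand_um)
  H <- nrow(lab)
  iy <- pmin(H, pmax(1L, as.integer(floor(sp$y_um / px)) + 1L))
  ix <- pmin(ncol(lab), pmax(1L, as.integer(floor(sp$x_um / px)) + 1L))
  lin <- (ix - 1L) * H + iy
  cellHit <- expanded[lin]
  onFdc <- fdcMask[lin]
  sp$assignment <- ifelse(cellHit > 0L, as.character(cellHit),
                          ifelse(onFdc, "fdc_bound", "unassigned"))
  out <- spots
  out@spots <- sp
  out
}

#' Expand a label map by a fixed radius
#'
#' Each background pixel within \code{radius_um} of a label is annexed to
#' its nearest label (Voronoi growth), emulating a cytoplasmic rim around
#' segmented nuclei.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param radius_um expansion radius in micrometres.
#' @return integer matrix of expanded labels.
#' @export
expandLabels <- function(labels, radius_um) {
  lab <- labelData(labels)
  px <- pixelSize(labels)
  if (max(lab) == 0L || radius_um <= 0) return(lab)
  dist <- EBImage::distmap(EBImage::Image((lab == 0L) * 1))
  mask <- matrix(as.numeric(dist), nrow(lab)) <= radius_um / px
  grown <- EBImage::propagate(EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
                              seeds = EBImage::Image(lab), mask = mask)
  matrix(as.integer(grown), nrow(lab))
}

#' Report vRNA burden per compartment and phenotype
#'
#' A cell is vRNA+ when at least one spot is assigned to it (mode
#' \code{"spots"}, the default) or when its mean vRNA intensity exceeds the
#' channel's gate cut (mode \code{"intensity"}). The report carries
#' per-follicle FDC-bound punctum counts, the fraction of each requested
#' gated population that is vRNA+ within follicular (F) and extrafollicular
#' (EF) scopes, and the share of total spot signal per compartment scope.
#'
#' @param spots a classified \linkS4class{SpotSet}.
#' @param cells a gated, compartment-annotated \linkS4class{CellTable}.
#' @param map the \linkS4class{CompartmentMap} (for follicle ids of
#'   FDC-bound spots and compartment signal shares).
#' @param populations gate node names to report rates for.
#' @param mode \code{"spots"} or \code{"intensity"}.
#' @param vrnaChannel channel name (intensity mode).
#' @param intensityCut cut for intensity mode.
#' @return list with \code{fdc_bound} (per-follicle counts),
#'   \code{cell_rates} (per population x scope) and \code{signal_share}
#'   (per scope), plus the \code{mode} used.
#' @export
reportVrna <- function(spots, cells, map,
                       populations = c("CD4hi", "CD4dim"),
                       mode = c("spots", "intensity"),
                       vrnaChannel = "vRNA", intensityCut = NULL) {
  mode <- match.arg(mode)
  sp <- spotData(spots)
  cc <- cellData(cells)
  px <- pixelSize(map)
  H <- nrow(regionData(map))

  vpos <- if (mode == "spots") {
    hit <- table(sp$assignment[!sp$assignment %in%
                                 c("fdc_bound", "unassigned")])
    cc$cell_id %in% as.integer(names(hit))
  } else {
    if (is.null(intensityCut))
      stop("intensity mode needs an intensityCut", call. = FALSE)
    cc[[paste0("mean_", vrnaChannel)]] > intensityCut
  }

  fdcSp <- sp[sp$assignment == "fdc_bound", , drop = FALSE]
  fid <- if (nrow(fdcSp)) {
    iy <- pmin(H, pmax(1L, as.integer(floor(fdcSp$y_um / px)) + 1L))
    ix <- pmin(ncol(regionData(map)),
               pmax(1L, as.integer(floor(fdcSp$x_um / px)) + 1L))
    follicleData(map)[(ix - 1L) * H + iy]
  } else integer(0)
  nF <- max(follicleData(map))
  fdcTab <- data.frame(follicle_id = seq_len(nF),
                       fdc_bound_count = tabulate(fid[fid > 0], nF))

  rates <- list()
  for (pop in populations) for (scope in c("F", "EF")) {
    m <- .scopeMask(cc, scope) & .gateCol(cc, pop)
    n <- sum(m)
    rates[[length(rates) + 1L]] <- data.frame(
      population = pop, scope = scope, n = n,
      vrna_pos = sum(m & vpos),
      pct_vrna_pos = if (n > 0) 100 * mean(vpos[m]) else NA_real_)
  }

  spScope <- if (nrow(sp)) {
    iy <- pmin(H, pmax(1L, as.integer(floor(sp$y_um / px)) + 1L))
    ix <- pmin(ncol(regionData(map)),
               pmax(1L, as.integer(floor(sp$x_um / px)) + 1L))
    reg <- regionData(map)[(ix - 1L) * H + iy]
    ifelse(reg == regionCodes()[["EF"]], "EF", "F")
  } else character(0)
  tot <- sum(sp$intensity)
  share <- data.frame(
    scope = c("F", "EF"),
    signal_share_pct = if (tot > 0)
      c(100 * sum(sp$intensity[spScope == "F"]) / tot,
        100 * sum(sp$intensity[spScope == "EF"]) / tot) else c(NA_real_, NA_real_))

  list(fdc_bound = fdcTab, cell_rates = do.call(rbind, rates),
       signal_share = share, mode = mode)
}
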