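# Maximum-intensity projection, nuclear segmentation and per-cell feature
# extraction (the HistoCytometry event table).

#' Maximum-intensity projection of a z-stack
#'
#' @param image a \linkS4class{MultichannelImage}; a 2D image is returned
#'   unchanged with a warning.
#' @return a single-plane \linkS4class{MultichannelImage} holding, per
#'   channel and (y, x), the maximum over z.
#' @export
projectMIP <- function(image) {
  if (!isStack(image)) {
    warning("image is already a single plane; returning unchanged")
    return(image)
  }
  d <- dim(image@data)
  out <- array(0, c(d[1], d[2], d[4]))
  for (k in seq_len(d[4]))
    out[, , k] <- apply(image@data[, , , k, drop = TRUE], c(1, 2), max)
  multichannelImage(out, channelNames(image), pixelSize(image),
                    metadata = c(image@metadata, list(projection = "mip")))
}

#' Segment nuclei from the nuclear channel
#'
#' Gaussian smoothing, global thresholding (Otsu by default), hole filling,
#' optional distance-transform watershed splitting of touching nuclei, size
#' filtering and contiguous relabelling.
#'
#' @param image a single-plane \linkS4class{MultichannelImage} (apply
#'   \code{\link{projectMIP}} to stacks first).
#' @param nuclearChannel name of the nuclear stain channel.
#' @param smooth_sigma_um Gaussian smoothing sigma in micrometres.
#' @param threshold \code{"otsu"} or a fixed intensity cut.
#' @param min_area_um2 components smaller than this are discarded (debris);
#'   the default is the area of a 2 um radius circle.
#' @param max_area_um2 components larger than this are discarded (merged
#'   clumps / lumen-bound signal not attached to a single nucleus);
#'   \code{NULL} defaults to 4x the median component area.
#' @param split split touching nuclei by watershed (default TRUE).
#' @param watershed_tolerance minimum object-separation depth (in distance
#'   map units) for the watershed split.
#' @return a \linkS4class{LabelMap}.
#' @export
segmentNuclei <- function(image, nuclearChannel,
                          smooth_sigma_um = 0.5,
                          threshold = "otsu",
                          min_area_um2 = pi * 2^2,
                          max_area_um2 = NULL,
                          split = TRUE,
                          watershed_tolerance = 0.2) {
  if (isStack(image))
    stop("segmentNuclei expects a single plane; apply projectMIP first",
         call. = FALSE)
  px <- pixelSize(image)
  plane <- getChannel(image, nuclearChannel)
  if (any(!is.finite(plane)))
    stop("nuclear channel contains non-finite pixels", call. = FALSE)
  sm <- gaussianBlur(plane, smooth_sigma_um, px)
  cut <- if (identical(threshold, "otsu")) otsuThreshold(sm) else
    as.numeric(threshold)
  bin <- sm > cut
  if (!any(bin)) {
    warning("empty foreground: no nuclei found")
    return(new("LabelMap", labels = matrix(0L, nrow(plane), ncol(plane)),
               pixelSize = px))
  }
  bin <- EBImage::fillHull(EBImage::Image(bin * 1))
  lab <- if (split) {
    dm <- EBImage::distmap(bin)
    EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  } else EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(plane))
  sizes <- tabulate(lab[lab > 0L])
  if (is.null(max_area_um2))
    max_area_um2 <- 4 * median(sizes) * px^2
  keep <- which(sizes * px^2 >= min_area_um2 & sizes * px^2 <= max_area_um2)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  new("LabelMap", labels = lab, pixelSize = px)
}

#' Extract per-cell features into a CellTable
#'
#' One record per label: mean intensity of every channel over the label's
#' pixels, centroid in micrometres (pixel-centre convention: a pixel at
#' 0-based index i spans [i, i+1) and has its centre at i + 0.5), area in
#' um^2 (exported as \code{volume_um2}) and circularity 4*pi*A/P^2 with a
#' Crofton perimeter estimate (exported as \code{sphericity}).
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param image the \linkS4class{MultichannelImage} the labels were derived
#'   from (same pixel grid).
#' @return a \linkS4class{CellTable} ordered by \code{cell_id}.
#' @export
extractFeatures <- function(labels, image) {
  lab <- labelData(labels)
  if (!identical(dim(lab), dim(image@data)[1:2]))
    stop("label map and image shapes differ", call. = FALSE)
  if (isStack(image))
    stop("extractFeatures expects a single plane; apply projectMIP first",
         call. = FALSE)
  px <- pixelSize(labels)
  K <- max(0L, max(lab))
  channels <- channelNames(image)
  if (K == 0L) {
    cells <- data.frame(cell_id = integer(0), x_um = numeric(0),
                        y_um = numeric(0), volume_um2 = numeric(0),
                        sphericity = numeric(0))
    for (ch in channels) cells[[paste0("mean_", ch)]] <- numeric(0)
    return(new("CellTable", cells = cells,
               provenance = .featureProvenance(image)))
  }
  pos <- which(lab > 0L)
  ids <- lab[pos]
  n <- tabulate(ids, K)
  rows <- ((pos - 1L) %% nrow(lab)) + 1L
  cols <- ((pos - 1L) %/% nrow(lab)) + 1L
  # pixel-centre convention: 0-based index + 0.5, scaled to micrometres
  yc <- rowsum(rows - 0.5, ids)[, 1] / n * px
  xc <- rowsum(cols - 0.5, ids)[, 1] / n * px
  per <- .croftonPerimeter(lab, K) * px
  area <- n * px^2
  cells <- data.frame(cell_id = seq_len(K), x_um = as.numeric(xc),
                      y_um = as.numeric(yc), volume_um2 = area,
                      sphericity = pmin(1.05, 4 * pi * area / per^2))
  for (ch in channels) {
    v <- getChannel(image, ch)
    cells[[paste0("mean_", ch)]] <- as.numeric(rowsum(v[pos], ids)[, 1] / n)
  }
  new("CellTable", cells = cells, provenance = .featureProvenance(image))
}

.featureProvenance <- function(image) {
  list(image_id = image@metadata$image_id %||% "unnamed",
       compensated = isTRUE(image@metadata$compensated),
       parameter_hash = rlang::hash(list(dim(image@data),
                                         channelNames(image))))
}

# Two-direction Crofton perimeter estimate: pi/4 times the number of
# foreground/other transitions along rows and columns, per label. Less
# pixelation-biased than boundary-pixel counting.
.croftonPerimeter <- function(lab, K) {
  counts <- numeric(K)
  tally <- function(a, b) {
    diff <- a != b
    ca <- a[diff]; cb <- b[diff]
    counts <<- counts + tabulate(ca[ca > 0L], K) + tabulate(cb[cb > 0L], K)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  tally(lab[, -nc], lab[, -1])
  tally(lab[-nr, ], lab[-1, ])
  # image border pixels contribute their exposed edges
  counts <- counts + tabulate(lab[c(1, nr), ][lab[c(1, nr), ] > 0L], K) +
    tabulate(lab[, c(1, nc)][lab[, c(1, nc)] > 0L], K)
  pi / 4 * counts
}
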