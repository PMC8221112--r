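#' @import methods
#' @importFrom stats median mad quantile rnorm rpois rlnorm runif dnorm setNames
#' @importFrom utils read.csv write.csv head
NULL

#' MultichannelImage: a fluorophore-indexed intensity array
#'
#' Container for a multispectral fluorescence image. Pixel data are stored as
#' a numeric array of dimension \code{(y, x, channel)} for a single plane or
#' \code{(y, x, z, channel)} for a z-stack, with non-negative intensities and
#' a physical pixel size in micrometres.
#'
#' @slot data numeric array, \code{(y, x, channel)} or \code{(y, x, z, channel)}.
#' @slot channelNames ordered, unique channel (fluorophore) names; length must
#'   equal the channel-axis extent.
#' @slot pixelSize physical size of one pixel in micrometres (> 0).
#' @slot zStep z spacing in micrometres; \code{numeric(0)} for a single plane.
#' @slot metadata free-form list (provenance, compensation flags, ...).
#' @exportClass MultichannelImage
setClass("MultichannelImage",
  representation(
    data = "array",
    channelNames = "character",
    pixelSize = "numeric",
    zStep = "numeric",
    metadata = "list"
  ),
  prototype(zStep = numeric(0), metadata = list())
)

setValidity("MultichannelImage", function(object) {
  d <- dim(object@data)
  msgs <- character(0)
  if (!length(d) %in% c(3L, 4L))
    msgs <- c(msgs, "data must be a 3D (y,x,channel) or 4D (y,x,z,channel) array")
  else {
    nch <- d[length(d)]
    if (length(object@channelNames) != nch)
      msgs <- c(msgs, sprintf("channelNames length (%d) != channel axis (%d)",
                              length(object@channelNames), nch))
    if (length(d) == 4L && length(object@zStep) != 1L)
      msgs <- c(msgs, "z-stacks require a scalar zStep")
  }
  if (anyDuplicated(object@channelNames))
    msgs <- c(msgs, "channel names must be unique")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a single positive number")
  if (any(object@data < 0, na.rm = TRUE))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SpilloverMatrix: fluorophore-by-channel mixing coefficients
#'
#' Square mixing matrix with rows indexing the emitting fluorophore and
#' columns the detection channel. The diagonal is exactly 1 and off-diagonal
#' entries lie in [0, 1]; the matrix must be invertible so that compensation
#' (solving \code{observed = t(M) \%*\% true} per pixel) is well defined.
#'
#' @slot coefficients numeric square matrix with matching row/column names.
#' @exportClass SpilloverMatrix
setClass("SpilloverMatrix", representation(coefficients = "matrix"))

setValidity("SpilloverMatrix", function(object) {
  m <- object@coefficients
  msgs <- character(0)
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "row and column names must be present and identical")
  if (nrow(m) > 0) {
    if (any(abs(diag(m) - 1) > 1e-12)) msgs <- c(msgs, "diagonal entries must equal 1")
    if (any(m < 0 | m > 1)) msgs <- c(msgs, "entries must lie in [0, 1]")
    k <- tryCatch(kappa(m, exact = FALSE), error = function(e) Inf)
    if (!is.finite(k) || k > 1e8) msgs <- c(msgs, "matrix is singular or ill-conditioned")
  }
  if (length(msgs)) msgs else TRUE
})

#' SceneGroundTruth: generated scene with per-cell truth
#'
#' The output of \code{\link{buildScene}}: cell positions, true phenotypes and
#' expression vectors, follicle/zone geometry, the FDC meshwork mask and the
#' true positions of every RNAscope punctum. Serves as the oracle against
#' which every recovery test of the analysis pipeline is scored.
#'
#' @slot cells data.frame, one row per cell: \code{id, y_um, x_um,
#'   nucleus_radius_um, phenotype, compartment, follicle_id, vrna_puncta}
#'   plus one \code{expr_<marker>} column per panel marker.
#' @slot follicles data.frame of ellipse parameters per follicle (centre,
#'   semi-axes, orientation, germinal-centre scale, dark-zone pole and offset).
#' @slot fdcMask logical matrix marking the FDC meshwork (pixel grid).
#' @slot fdcPuncta data.frame of FDC-bound punctum centres (\code{y_um, x_um,
#'   follicle_id}).
#' @slot cellPuncta data.frame of cell-associated punctum centres
#'   (\code{y_um, x_um, cell_id}).
#' @slot config the validated scene configuration list used for generation.
#' @exportClass SceneGroundTruth
setClass("SceneGroundTruth",
  representation(
    cells = "data.frame",
    follicles = "data.frame",
    fdcMask = "matrix",
    fdcPuncta = "data.frame",
    cellPuncta = "data.frame",
    config = "list"
  )
)

setValidity("SceneGroundTruth", function(object) {
  msgs <- character(0)
  cc <- object@cells
  need <- c("id", "y_um", "x_um", "nucleus_radius_um", "phenotype",
            "compartment", "follicle_id", "vrna_puncta")
  miss <- setdiff(need, names(cc))
  if (length(miss)) msgs <- c(msgs, paste("cells missing columns:",
                                          paste(miss, collapse = ", ")))
  if (nrow(cc) && anyDuplicated(cc$id)) msgs <- c(msgs, "cell ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' LabelMap: integer segmentation label image
#'
#' @slot labels integer matrix; 0 = background, k > 0 = cell k. Labels are
#'   contiguous positive integers starting at 1.
#' @slot pixelSize micrometres per pixel.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "matrix", pixelSize = "numeric"))

setValidity("LabelMap", function(object) {
  msgs <- character(0)
  lab <- object@labels
  if (any(lab < 0)) msgs <- c(msgs, "labels must be non-negative")
  mx <- suppressWarnings(max(lab))
  if (mx > 0) {
    present <- sort(unique(lab[lab > 0]))
    if (!identical(as.integer(present), seq_len(mx)))
      msgs <- c(msgs, "labels must be contiguous integers 1..K")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' CellTable: the HistoCytometry event table
#'
#' One row per segmented cell with centroid, area (exported under the column
#' name \code{volume_um2} for compatibility with the HistoCytometry
#' spreadsheet vocabulary), circularity (exported as \code{sphericity}), the
#' mean intensity of every channel over the cell's pixels, and -- once
#' assigned/gated -- a compartment label and gate membership columns.
#'
#' @slot cells data.frame with columns \code{cell_id, x_um, y_um, volume_um2,
#'   sphericity}, one \code{mean_<channel>} column per channel, and optional
#'   \code{region}, \code{follicle_id} and \code{gate_<node>} columns.
#' @slot provenance list (image id, seed, parameter hash, ...).
#' @exportClass CellTable
setClass("CellTable",
  representation(cells = "data.frame", provenance = "list"),
  prototype(provenance = list())
)

setValidity("CellTable", function(object) {
  msgs <- character(0)
  cc <- object@cells
  need <- c("cell_id", "x_um", "y_um", "volume_um2", "sphericity")
  miss <- setdiff(need, names(cc))
  if (length(miss)) msgs <- c(msgs, paste("missing columns:",
                                          paste(miss, collapse = ", ")))
  if (nrow(cc)) {
    if (anyDuplicated(cc$cell_id)) msgs <- c(msgs, "cell_id values must be unique")
    if (all(c("volume_um2") %in% names(cc)) && any(cc$volume_um2 <= 0))
      msgs <- c(msgs, "areas must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' CompartmentMap: microanatomical region labelling of the pixel grid
#'
#' Region codes partition the field into extrafollicular space (EF), mantle
#' zone (MZ), light zone (LZ) and dark zone (DZ); the germinal centre is
#' LZ + DZ and a follicle is MZ + GC. \code{follicleIds} gives the follicle
#' instance (0 = extrafollicular) per pixel.
#'
#' @slot regionCodes integer matrix of codes (see \code{\link{regionCodes}}).
#' @slot follicleIds integer matrix, 0 outside follicles.
#' @slot pixelSize micrometres per pixel.
#' @exportClass CompartmentMap
setClass("CompartmentMap",
  representation(regionCodes = "matrix", follicleIds = "matrix",
                 pixelSize = "numeric"))

setValidity("CompartmentMap", function(object) {
  msgs <- character(0)
  rc <- object@regionCodes; fi <- object@follicleIds
  if (!identical(dim(rc), dim(fi)))
    msgs <- c(msgs, "regionCodes and follicleIds must share a pixel grid")
  codes <- regionCodes()
  if (!all(rc %in% codes))
    msgs <- c(msgs, "regionCodes contains values outside the EF/MZ/LZ/DZ code set")
  inF <- rc != codes[["EF"]]
  if (any(fi[inF] == 0)) msgs <- c(msgs, "MZ/LZ/DZ pixels must carry a follicle id")
  if (any(fi[!inF] != 0)) msgs <- c(msgs, "EF pixels must have follicle id 0")
  if (length(msgs)) msgs else TRUE
})

#' ThresholdSet: per-channel lo/dim/hi cutpoints
#'
#' One or two strictly increasing cutpoints per channel. A single cut splits
#' a channel into -/+ (lo/hi); two cuts define lo/dim/hi.
#'
#' @slot cuts named list of numeric vectors (length 1 or 2) on the raw
#'   intensity scale.
#' @slot method named character vector recording the derivation method per
#'   channel.
#' @slot parameters list of method parameters.
#' @exportClass ThresholdSet
setClass("ThresholdSet",
  representation(cuts = "list", method = "character", parameters = "list"),
  prototype(parameters = list())
)

setValidity("ThresholdSet", function(object) {
  msgs <- character(0)
  if (is.null(names(object@cuts)) || any(!nzchar(names(object@cuts))))
    msgs <- c(msgs, "cuts must be a named list")
  for (ch in names(object@cuts)) {
    v <- object@cuts[[ch]]
    if (!length(v) %in% 1:2 || any(!is.finite(v)) || is.unsorted(v, strictly = TRUE))
      msgs <- c(msgs, sprintf("channel '%s': cutpoints must be 1-2 strictly increasing finite values", ch))
  }
  if (length(msgs)) msgs else TRUE
})

#' GateTree: a hierarchical gating strategy
#'
#' A rooted tree of named gates. Each non-root node carries a predicate:
#' a conjunction of channel terms (level in lo/dim/hi/+/-/"hi/dim") and/or
#' feature terms on event-table columns (e.g. \code{volume_um2 >= "median"}).
#' A cell belongs to a node iff it satisfies the predicates of the node and
#' all its ancestors.
#'
#' @slot name tree (panel) name.
#' @slot nodes named list; each element has \code{parent} (character, "" for
#'   the root), \code{channels} (named character of levels) and optionally
#'   \code{features} (list of \code{list(column, op, value)}).
#' @exportClass GateTree
setClass("GateTree", representation(name = "character", nodes = "list"))

setValidity("GateTree", function(object) {
  msgs <- character(0)
  nd <- object@nodes
  if (is.null(names(nd)) || anyDuplicated(names(nd)))
    msgs <- c(msgs, "node names must be present and unique")
  roots <- names(nd)[vapply(nd, function(n) identical(n$parent, ""), logical(1))]
  if (length(roots) != 1L) msgs <- c(msgs, "exactly one root node is required")
  for (nm in names(nd)) {
    p <- nd[[nm]]$parent
    if (!identical(p, "") && !p %in% names(nd))
      msgs <- c(msgs, sprintf("node '%s' references unknown parent '%s'", nm, p))
    lv <- nd[[nm]]$channels
    bad <- setdiff(unname(lv), c("lo", "dim", "hi", "+", "-", "hi/dim"))
    if (length(bad))
      msgs <- c(msgs, sprintf("node '%s': invalid level(s) %s", nm,
                              paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' SpotSet: detected RNAscope puncta
#'
#' @slot spots data.frame with columns \code{spot_id, y_um, x_um, radius_um,
#'   intensity, assignment} (assignment is \code{"unassigned"},
#'   \code{"fdc_bound"} or a cell id as character) .
#' @slot pixelSize micrometres per pixel of the source image.
#' @exportClass SpotSet
setClass("SpotSet",
  representation(spots = "data.frame", pixelSize = "numeric"))

setValidity("SpotSet", function(object) {
  msgs <- character(0)
  sp <- object@spots
  need <- c("spot_id", "y_um", "x_um", "radius_um", "intensity", "assignment")
  miss <- setdiff(need, names(sp))
  if (length(miss)) msgs <- c(msgs, paste("spots missing columns:",
                                          paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(sp) && any(sp$radius_um <= 0))
    msgs <- c(msgs, "radii must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Region code lookup
#'
#' Integer codes used in \linkS4class{CompartmentMap} region images:
#' EF = 1, MZ = 2, LZ = 3, DZ = 4. The germinal centre is the union of LZ
#' and DZ; a follicle is MZ plus GC.
#'
#' @return named integer vector.
#' @export
regionCodes <- function() c(EF = 1L, MZ = 2L, LZ = 3L, DZ = 4L)
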