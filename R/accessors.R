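# Constructors, accessors and show methods for the core containers.

#' Construct a MultichannelImage
#'
#' @param data numeric array \code{(y, x, channel)} or \code{(y, x, z,
#'   channel)}; a plain matrix is promoted to a single-channel plane.
#' @param channelNames character vector of channel names.
#' @param pixelSize micrometres per pixel.
#' @param zStep z spacing in micrometres (z-stacks only).
#' @param metadata optional provenance list.
#' @return a \linkS4class{MultichannelImage}.
#' @examples
#' img <- multichannelImage(array(runif(32), c(4, 4, 2)),
#'                          c("DNA", "CD20"), pixelSize = 0.5)
#' channelNames(img)
#' @export
multichannelImage <- function(data, channelNames, pixelSize, zStep = numeric(0),
                              metadata = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("MultichannelImage", data = data, channelNames = as.character(channelNames),
      pixelSize = as.numeric(pixelSize), zStep = as.numeric(zStep),
      metadata = metadata)
}

#' @rdname MultichannelImage-class
#' @export
setMethod("channelNames", "MultichannelImage", function(x) x@channelNames)

#' @rdname MultichannelImage-class
#' @export
setMethod("pixelSize", "MultichannelImage", function(x) x@pixelSize)

#' @rdname MultichannelImage-class
#' @export
setMethod("pixelSize", "LabelMap", function(x) x@pixelSize)

#' @rdname MultichannelImage-class
#' @export
setMethod("pixelSize", "CompartmentMap", function(x) x@pixelSize)

#' @rdname MultichannelImage-class
#' @export
setMethod("nChannels", "MultichannelImage",
          function(x) dim(x@data)[length(dim(x@data))])

#' @rdname MultichannelImage-class
#' @export
setMethod("isStack", "MultichannelImage",
          function(x) length(dim(x@data)) == 4L)

#' @rdname MultichannelImage-class
#' @export
setMethod("getChannel", "MultichannelImage", function(x, channel) {
  idx <- .channelIndex(x, channel)
  if (isStack(x)) x@data[, , , idx] else x@data[, , idx]
})

.channelIndex <- function(x, channel) {
  if (is.character(channel)) {
    idx <- match(channel, x@channelNames)
    if (anyNA(idx))
      stop("unknown channel(s): ", paste(channel[is.na(idx)], collapse = ", "),
           call. = FALSE)
    idx
  } else as.integer(channel)
}

setMethod("show", "MultichannelImage", function(object) {
  d <- dim(object@data)
  cat("MultichannelImage:", paste(d[1:2], collapse = " x "), "px",
      if (isStack(object)) sprintf("x %d z-slices", d[3]) else "",
      sprintf("(%.3g um/px)\n", object@pixelSize))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Construct a SpilloverMatrix
#'
#' @param coefficients square numeric matrix, rows = emitting fluorophore,
#'   columns = detection channel; dimnames must match.
#' @return a \linkS4class{SpilloverMatrix}.
#' @examples
#' m <- diag(2); dimnames(m) <- list(c("A", "B"), c("A", "B"))
#' spilloverMatrix(m)
#' @export
spilloverMatrix <- function(coefficients) {
  new("SpilloverMatrix", coefficients = coefficients)
}

#' @rdname SpilloverMatrix-class
#' @export
setMethod("spilloverCoefficients", "SpilloverMatrix",
          function(x) x@coefficients)

setMethod("show", "SpilloverMatrix", function(object) {
  cat("SpilloverMatrix over", nrow(object@coefficients), "fluorophores\n")
  print(round(object@coefficients, 4))
})

#' @rdname CellTable-class
#' @export
setMethod("cellData", "CellTable", function(x) x@cells)

#' @rdname CellTable-class
#' @export
setMethod("provenance", "CellTable", function(x) x@provenance)

setMethod("show", "CellTable", function(object) {
  cat("CellTable with", nrow(object@cells), "cells\n")
  ch <- grep("^mean_", names(object@cells), value = TRUE)
  cat("  channels:", paste(sub("^mean_", "", ch), collapse = ", "), "\n")
  gt <- grep("^gate_", names(object@cells), value = TRUE)
  if (length(gt)) cat("  gates:", length(gt), "nodes\n")
  if ("region" %in% names(object@cells)) cat("  compartments assigned\n")
})

#' @rdname LabelMap-class
#' @export
setMethod("labelData", "LabelMap", function(x) x@labels)

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap:", paste(dim(object@labels), collapse = " x "), "px,",
      max(0L, max(object@labels)), "labels\n")
})

#' @rdname CompartmentMap-class
#' @export
setMethod("regionData", "CompartmentMap", function(x) x@regionCodes)

#' @rdname CompartmentMap-class
#' @export
setMethod("follicleData", "CompartmentMap", function(x) x@follicleIds)

setMethod("show", "CompartmentMap", function(object) {
  codes <- regionCodes()
  px <- object@pixelSize^2
  cat("CompartmentMap:", paste(dim(object@regionCodes), collapse = " x "), "px,",
      max(object@follicleIds), "follicle(s)\n")
  for (r in names(codes))
    cat(sprintf("  %s: %.3g mm2\n", r,
                sum(object@regionCodes == codes[[r]]) * px / 1e6))
})

#' @rdname SceneGroundTruth-class
#' @export
setMethod("groundTruthCells", "SceneGroundTruth", function(x) x@cells)

setMethod("show", "SceneGroundTruth", function(object) {
  cat("SceneGroundTruth:", nrow(object@cells), "cells,",
      nrow(object@follicles), "follicle(s)\n")
  print(table(object@cells$compartment))
})

#' @rdname SpotSet-class
#' @export
setMethod("spotData", "SpotSet", function(x) x@spots)

setMethod("show", "SpotSet", function(object) {
  cat("SpotSet with", nrow(object@spots), "puncta\n")
  if (nrow(object@spots)) print(table(.assignmentClass(object@spots$assignment)))
})

.assignmentClass <- function(a) {
  ifelse(a %in% c("unassigned", "fdc_bound"), a, "cell")
}

#' @rdname ThresholdSet-class
#' @export
setMethod("thresholdCuts", "ThresholdSet", function(x) x@cuts)

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet for", length(object@cuts), "channel(s)\n")
  for (ch in names(object@cuts))
    cat(sprintf("  %s [%s]: %s\n", ch, object@method[[ch]],
                paste(signif(object@cuts[[ch]], 4), collapse = ", ")))
})

#' Construct a ThresholdSet from fixed cutpoints
#'
#' @param cuts named list of numeric cut vectors (1 or 2 increasing values
#'   per channel) on the raw intensity scale.
#' @param method derivation tag recorded per channel (default "fixed").
#' @return a \linkS4class{ThresholdSet}.
#' @examples
#' thresholdSet(list(CD20 = c(10, 100), CD4 = 25))
#' @export
thresholdSet <- function(cuts, method = "fixed") {
  if (length(method) == 1L) method <- setNames(rep(method, length(cuts)),
                                               names(cuts))
  new("ThresholdSet", cuts = lapply(cuts, as.numeric), method = method)
}
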