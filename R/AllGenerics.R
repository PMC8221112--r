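#' @rdname MultichannelImage-class
#' @param object,x a \linkS4class{MultichannelImage} (or other class as
#'   documented per method).
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname MultichannelImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname MultichannelImage-class
#' @param channel channel name or index.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname MultichannelImage-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname MultichannelImage-class
#' @export
setGeneric("isStack", function(x) standardGeneric("isStack"))

#' @rdname SpilloverMatrix-class
#' @export
setGeneric("spilloverCoefficients",
           function(x) standardGeneric("spilloverCoefficients"))

#' @rdname CellTable-class
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname CellTable-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname LabelMap-class
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname CompartmentMap-class
#' @export
setGeneric("regionData", function(x) standardGeneric("regionData"))

#' @rdname CompartmentMap-class
#' @export
setGeneric("follicleData", function(x) standardGeneric("follicleData"))

#' @rdname SceneGroundTruth-class
#' @export
setGeneric("groundTruthCells", function(x) standardGeneric("groundTruthCells"))

#' @rdname SpotSet-class
#' @export
setGeneric("spotData", function(x) standardGeneric("spotData"))

#' @rdname ThresholdSet-class
#' @export
setGeneric("thresholdCuts", function(x) standardGeneric("thresholdCuts"))
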