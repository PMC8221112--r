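# File I/O: multichannel TIFF with channel metadata, spillover CSV,
# event-table CSV, compartment-map export and YAML configuration.

#' Write a MultichannelImage as a multi-page TIFF with a metadata sidecar
#'
#' One 16-bit page per channel. Channel names and the physical pixel size
#' are written to an OME-style JSON sidecar (\code{<path>.meta.json}),
#' since the TIFF writer in use does not expose the image-description tag.
#' Intensities are clipped to [0, 65535] and stored as uint16.
#'
#' @param image a single-plane \linkS4class{MultichannelImage}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMultichannelTIFF <- function(image, path) {
  if (isStack(image))
    stop("TIFF export supports single planes; apply projectMIP first",
         call. = FALSE)
  pages <- lapply(seq_len(nChannels(image)), function(k)
    pmin(pmax(image@data[, , k], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(channels = channelNames(image),
         physical_size_um = pixelSize(image), type = "uint16"),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by \code{writeMultichannelTIFF}
#'
#' @param path TIFF file path (the \code{.meta.json} sidecar is read when
#'   present; otherwise channels are named \code{ch1..chN} at 1 um/px).
#' @return a \linkS4class{MultichannelImage} on the stored intensity scale.
#' @export
readMultichannelTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(paste0(path, ".meta.json")))
    jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  else list()
  nm <- meta$channels %||% paste0("ch", seq_along(pages))
  ps <- meta$physical_size_um %||% 1
  first <- pages[[1]]
  arr <- array(0, c(dim(first)[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , k] <- pg * 65535
  }
  multichannelImage(arr, nm, ps)
}

#' Spillover matrix CSV round-trip
#'
#' Full-precision CSV with a header row/column of fluorophore/channel
#' names; values survive a write/read round-trip bit-exactly.
#'
#' @param matrix a \linkS4class{SpilloverMatrix}.
#' @param path CSV path.
#' @return \code{writeSpilloverCSV}: the path, invisibly.
#' @export
writeSpilloverCSV <- function(matrix, path) {
  m <- spilloverCoefficients(matrix)
  lines <- c(paste(c("fluorophore", colnames(m)), collapse = ","),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSpilloverCSV
#' @export
readSpilloverCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  spilloverMatrix(m)
}

#' Event-table CSV round-trip
#'
#' Writes the HistoCytometry "unified spreadsheet": one row per cell with
#' \code{cell_id, x_um, y_um, volume_um2, sphericity}, one mean-intensity
#' column per channel, then compartment and gate columns.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param path CSV path.
#' @return \code{writeCellTableCSV}: the path, invisibly.
#' @export
writeCellTableCSV <- function(cells, path) {
  write.csv(cellData(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellTableCSV
#' @export
readCellTableCSV <- function(path) {
  cc <- read.csv(path, check.names = FALSE)
  for (col in grep("^(gate_|tzone)", names(cc), value = TRUE))
    cc[[col]] <- as.logical(cc[[col]])
  new("CellTable", cells = cc, provenance = list(source = path))
}

#' Export a CompartmentMap
#'
#' Writes the region-code and follicle-id images as 16-bit TIFFs plus a
#' JSON legend mapping codes to region names.
#'
#' @param map a \linkS4class{CompartmentMap}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the legend path, invisibly.
#' @export
writeCompartmentMap <- function(map, dir, prefix = "compartments") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(regionData(map) / 65535, file.path(dir,
    paste0(prefix, "_regions.tif")), bits.per.sample = 16L)
  tiff::writeTIFF(follicleData(map) / 65535, file.path(dir,
    paste0(prefix, "_follicles.tif")), bits.per.sample = 16L)
  legend <- file.path(dir, paste0(prefix, "_legend.json"))
  jsonlite::write_json(list(region_codes = as.list(regionCodes()),
                            pixel_size_um = pixelSize(map)),
                       legend, auto_unbox = TRUE)
  invisible(legend)
}

#' Read a scene + optics fixture from YAML
#'
#' The YAML mirrors the \code{\link{sceneConfig}} arguments under
#' \code{scene:} and the \code{\link{opticsConfig}} arguments under
#' \code{optics:} (with the spillover matrix given as \code{channels} and a
#' row-major \code{matrix}).
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the one stored in the file.
#' @return list with \code{scene} (a \code{"SceneConfig"}) and
#'   \code{optics} (an \code{"OpticsConfig"}).
#' @export
readSceneYAML <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sc <- y$scene
  if (!is.null(seed)) sc$seed <- seed
  for (f in c("field_size_um", "follicle_axes_um", "axis_ratio_range",
              "nuclear_intensity", "nucleus_radius_um"))
    if (!is.null(sc[[f]])) sc[[f]] <- as.numeric(sc[[f]])
  if (!is.null(sc$phenotype_profiles))
    sc$phenotype_profiles <- lapply(sc$phenotype_profiles,
                                    function(p) lapply(p, as.numeric))
  scene <- do.call(sceneConfig, sc)
  optics <- NULL
  if (!is.null(y$optics)) {
    o <- y$optics
    ch <- o$spillover$channels
    m <- do.call(rbind, lapply(o$spillover$matrix, as.numeric))
    dimnames(m) <- list(ch, ch)
    optics <- opticsConfig(
      spillover = spilloverMatrix(m),
      psf_sigma_um = o$psf_sigma_um %||% 0.8,
      autofluorescence = unlist(o$autofluorescence %||% 3),
      noise = o$noise %||% list(gaussian_sd = 1.5, poisson_scale = 0.5),
      bit_depth = o$bit_depth %||% 16L)
  }
  list(scene = scene, optics = optics)
}

#' Read a panel definition from YAML
#'
#' A panel bundles the channel list, per-channel threshold derivation
#' specs, the hierarchical gate tree, the compartment marker mapping and
#' the default quantification requests.
#'
#' @param path YAML file path.
#' @return list with \code{name}, \code{channels}, \code{thresholds},
#'   \code{tree} (a \linkS4class{GateTree}), \code{compartment_markers} and
#'   \code{quantify} (list of population/scope/denominator requests).
#' @export
readPanelYAML <- function(path) {
  y <- yaml::read_yaml(path)
  tree <- gateTree(y$name, y$gates)
  list(name = y$name, channels = y$channels,
       thresholds = y$thresholds,
       tree = tree,
       compartment_markers = y$compartment_markers,
       compartment_params = y$compartment_params,
       structural_markers = y$structural_markers,
       quantify = y$quantify)
}

#' Shipped reference fixtures
#'
#' \code{referencePanel} and \code{referenceScene} load the panel and scene
#' fixtures installed with the package; \code{listFixtures} enumerates
#' them.
#'
#' @param name fixture name (e.g. \code{"gc_reference"},
#'   \code{"treg_reference"}); see \code{listFixtures()}.
#' @param seed optional seed override for scenes.
#' @return see \code{\link{readPanelYAML}} / \code{\link{readSceneYAML}}.
#' @export
referencePanel <- function(name) {
  path <- system.file("extdata", "panels", paste0(name, ".yaml"),
                      package = "HistoCyto", mustWork = TRUE)
  readPanelYAML(path)
}

#' @rdname referencePanel
#' @export
referenceScene <- function(name, seed = NULL) {
  path <- system.file("extdata", "scenes", paste0(name, ".yaml"),
                      package = "HistoCyto", mustWork = TRUE)
  readSceneYAML(path, seed = seed)
}

#' @rdname referencePanel
#' @export
listFixtures <- function() {
  list(
    panels = sub("\\.yaml$", "", list.files(
      system.file("extdata", "panels", package = "HistoCyto"), "\\.yaml$")),
    scenes = sub("\\.yaml$", "", list.files(
      system.file("extdata", "scenes", package = "HistoCyto"), "\\.yaml$")))
}
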