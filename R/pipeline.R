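# End-to-end pipeline: simulate/load -> compensate -> (AF-subtract) ->
# (MIP) -> segment -> features -> compartments -> thresholds -> gates ->
# quantify -> (RNAscope).

#' Derive a small single-stain control scene from a scene configuration
#'
#' Single-stain controls are acquired once per panel under the same
#' staining and acquisition conditions; the control scene is a small plain
#' field with a uniform phenotype mixture, so every fluorophore has an
#' abundant positive population to regress on.
#'
#' @param cfg a \code{"SceneConfig"}.
#' @param field_um control field edge length.
#' @param density_mm2 control cell density.
#' @return a \code{"SceneConfig"} for the control scene.
#' @export
controlSceneConfig <- function(cfg, field_um = 500, density_mm2 = 2500) {
  cfg$field_size_um <- c(field_um, field_um)
  cfg$n_follicles <- 0L
  # controls are chosen so every stain has abundant positives: a uniform
  # phenotype mixture on a plain field
  ph <- names(cfg$phenotype_profiles)
  cfg$composition <- list(EF = setNames(rep(1 / length(ph), length(ph)), ph))
  cfg$cell_density_mm2 <- c(EF = density_mm2, MZ = 0, LZ = 0, DZ = 0)
  cfg$fdc_density <- 0
  cfg$structural_channels <- list()
  cfg$vrna <- NULL
  cfg$seed <- deriveSeed(cfg$seed, "control")
  validateSceneConfig(cfg)
  cfg
}

# FDC-dense mask from the imaged FDC channel (light smoothing + Otsu).
.fdcHiMask <- function(image, channel, smooth_um = 1.5) {
  sm <- gaussianBlur(getChannel(image, channel), smooth_um,
                     pixelSize(image))
  if (diff(range(sm)) < 1e-9) return(sm > Inf)
  sm > otsuThreshold(sm)
}

#' Run the full HistoCytometry pipeline on a synthetic scene
#'
#' Renders (or accepts) a multichannel image, applies spillover
#' compensation, segments nuclei, extracts the event table, maps
#' compartments, derives thresholds, applies the panel's gate tree,
#' quantifies the configured populations and (when the panel carries a vRNA
#' channel) runs punctum detection, classification and vRNA reporting.
#' All stage randomness derives from a single seed, so identical
#' configuration and seed give identical outputs.
#'
#' @param scene a \code{"SceneConfig"}, a list
#'   \code{list(scene=, optics=)} as returned by \code{\link{readSceneYAML}}
#'   / \code{\link{referenceScene}}, or a path to a scene YAML.
#' @param panel a panel name (shipped fixture), path to a panel YAML, or a
#'   list from \code{\link{readPanelYAML}}.
#' @param seed optional seed overriding the scene's.
#' @param optics an \code{"OpticsConfig"} (required when \code{scene} does
#'   not bundle one).
#' @param spillover \code{NULL} (use the acquisition's known matrix, i.e.
#'   the optics spillover), \code{"estimate"} (render single-stain controls
#'   and estimate it), a \linkS4class{SpilloverMatrix}, or \code{FALSE} to
#'   skip compensation.
#' @param stages named logical toggles: \code{compensate}, \code{segment},
#'   \code{compartments}, \code{gates}, \code{quantify}, \code{rnascope},
#'   \code{areas}. Disabled stages are logged as skipped.
#' @param params named list of stage parameter overrides:
#'   \code{segment}, \code{compartments}, \code{spots} (passed to the
#'   respective functions).
#' @param scopedGates derive intensity thresholds separately within each
#'   compartment context (EF / MZ / GC) for the mode-based (kde/gmm)
#'   channels, mirroring per-locality manual gating; channels with
#'   background-anchored methods keep global cuts. Requires compartment
#'   assignment; falls back to global gating otherwise.
#' @param zSlices render a thin z-stack and apply MIP when > 1.
#' @param outputDir optional directory; when given, the event table,
#'   quantification report, compartment map, spot table and provenance are
#'   written there.
#' @param verbose log stage progress.
#' @return list with \code{image}, \code{labels}, \code{cells},
#'   \code{map}, \code{thresholds}, \code{quant}, \code{areas},
#'   \code{spots}, \code{vrna}, \code{scene}, \code{provenance}.
#' @export
runPipeline <- function(scene, panel, seed = NULL, optics = NULL,
                        spillover = NULL,
                        stages = list(), params = list(),
                        scopedGates = TRUE,
                        zSlices = 1L, outputDir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  st <- function(name, default = TRUE) {
    on <- stages[[name]] %||% default
    if (!on) say("stage '", name, "' skipped")
    on
  }
  fail <- function(stage, e) {
    if (!is.null(outputDir)) {
      dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
      writeLines(c(stage, conditionMessage(e)),
                 file.path(outputDir, "FAILED"))
    }
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  run <- function(stage, expr) tryCatch(expr, error = function(e)
    fail(stage, e))

  # ---- resolve inputs
  if (is.character(scene)) scene <- readSceneYAML(scene)
  if (is.list(scene) && !is.null(scene$scene)) {
    optics <- optics %||% scene$optics
    scene <- scene$scene
  }
  if (!inherits(scene, "SceneConfig"))
    stop("scene must be a SceneConfig, a fixture list or a YAML path",
         call. = FALSE)
  if (is.null(optics)) stop("an optics configuration is required",
                            call. = FALSE)
  if (is.character(panel) && file.exists(panel)) panel <- readPanelYAML(panel)
  else if (is.character(panel)) panel <- referencePanel(panel)
  if (!is.null(seed)) scene$seed <- as.integer(seed)

  say("simulate: building + rendering scene (seed ", scene$seed, ")")
  gt <- run("simulate", buildScene(scene))
  img <- run("simulate", renderScene(gt, optics, zSlices = zSlices))
  img@metadata$image_id <- sprintf("%s_seed%d", panel$name, scene$seed)

  # ---- compensation
  spill <- NULL
  if (st("compensate")) {
    spill <- run("compensate", {
      if (isFALSE(spillover)) NULL
      else if (is(spillover, "SpilloverMatrix")) spillover
      else if (identical(spillover, "estimate")) {
        say("compensate: estimating spillover from single-stain controls")
        ctrl <- buildScene(controlSceneConfig(scene))
        estimateSpillover(renderSingleStains(ctrl, optics),
                          foregroundQuantile = 0.997)
      } else optics$spillover
    })
    if (!is.null(spill)) img <- run("compensate", compensate(img, spill))
  }

  if (isStack(img)) img <- run("mip", projectMIP(img))

  # ---- segmentation + features
  labels <- cells <- NULL
  if (st("segment")) {
    say("segment: nuclear segmentation")
    labels <- run("segment", do.call(segmentNuclei, c(
      list(image = img, nuclearChannel = scene$nuclear_channel),
      params$segment %||% list())))
    cells <- run("features", extractFeatures(labels, img))
    cells@provenance$seed <- scene$seed
  }

  # ---- compartments
  map <- NULL
  if (st("compartments") && !is.null(cells)) {
    say("compartments: building map")
    cm <- panel$compartment_markers
    invert <- isTRUE(cm$invert_cd20)
    cm$invert_cd20 <- NULL
    cpar <- panel$compartment_params %||% list()
    over <- params$compartments %||% list()
    cpar[names(over)] <- over
    map <- run("compartments", do.call(buildCompartmentMap, c(
      list(image = img, markers = cm, invert_follicle_marker = invert),
      cpar)))
    cells <- run("compartments", assignCompartments(cells, map))
  }

  # ---- thresholds + gates
  thr <- NULL
  if (st("gates") && !is.null(cells)) {
    say("gates: deriving thresholds and applying the gate tree")
    thrSeed <- deriveSeed(scene$seed, "thresholds")
    if (scopedGates && "region" %in% names(cellData(cells))) {
      gated <- run("gates", .scopedGating(cells, panel, thrSeed))
      cells <- gated$cells
      thr <- gated$thresholds
    } else {
      thr <- run("thresholds",
                 deriveThresholds(cells, panel$thresholds, seed = thrSeed))
      cells <- run("gates", applyGates(cells, panel$tree, thr))
    }
  }

  # ---- areas + quantification
  areas <- NULL
  if (st("areas", default = !is.null(panel$structural_markers)) &&
      !is.null(map)) {
    sm <- panel$structural_markers %||% list(nuclear = scene$nuclear_channel)
    areas <- run("areas", quantifyAreas(map, img, sm))
  }
  quant <- NULL
  if (st("quantify") && !is.null(cells) && length(panel$quantify)) {
    quant <- run("quantify", quantifyPopulations(
      cells, panel$quantify,
      tissueAreaUm2 = areas$total_tissue_area_um2 %||% NULL))
  }

  # ---- RNAscope
  spots <- vrna <- NULL
  hasVrna <- !is.null(scene$vrna) &&
    (scene$vrna$channel %in% channelNames(img))
  if (st("rnascope", default = hasVrna)) {
    if (!hasVrna)
      say("rnascope enabled but the scene carries no vRNA channel; skipping")
    else {
      say("rnascope: punctum detection and classification")
      spots <- run("rnascope", do.call(detectSpots, c(
        list(image = img, vrnaChannel = scene$vrna$channel),
        params$spots %||% list())))
      fdcMask <- .fdcHiMask(img, "FDC")
      spots <- run("rnascope", classifySpots(spots, labels, fdcMask))
      vrna <- run("rnascope", reportVrna(spots, cells, map))
    }
  }

  prov <- list(panel = panel$name, seed = scene$seed,
               parameter_hash = rlang::hash(list(scene, params)),
               package_version = as.character(utils::packageVersion("HistoCyto")))

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(cells)) writeCellTableCSV(cells,
      file.path(outputDir, "cells.csv"))
    if (!is.null(quant)) write.csv(quant,
      file.path(outputDir, "quantification.csv"), row.names = FALSE)
    if (!is.null(map)) writeCompartmentMap(map, outputDir)
    if (!is.null(areas)) {
      write.csv(areas$follicles, file.path(outputDir, "areas_follicles.csv"),
                row.names = FALSE)
      write.csv(areas$field, file.path(outputDir, "areas_field.csv"),
                row.names = FALSE)
    }
    if (!is.null(spots)) write.csv(spotData(spots),
      file.path(outputDir, "spots.csv"), row.names = FALSE)
    if (!is.null(vrna)) {
      write.csv(vrna$fdc_bound, file.path(outputDir, "vrna_fdc_bound.csv"),
                row.names = FALSE)
      write.csv(vrna$cell_rates, file.path(outputDir, "vrna_cell_rates.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(prov, file.path(outputDir, "provenance.json"),
                         auto_unbox = TRUE)
  }

  list(image = img, labels = labels, cells = cells, map = map,
       thresholds = thr, quant = quant, areas = areas, spots = spots,
       vrna = vrna, scene = gt, spillover = spill, provenance = prov)
}


# Scope-stratified gating: kde/gmm channel cuts are re-derived within each
# compartment context (ambient staining differs strongly between EF, MZ
# and GC), while background-anchored channels keep their global cuts.
.scopedGating <- function(cells, panel, seed, minScopeCells = 300) {
  cc <- cellData(cells)
  spec <- panel$thresholds
  globalThr <- deriveThresholds(cells, spec, seed = seed)
  scopeCls <- ifelse(cc$region == "EF", "EF",
                     ifelse(cc$region == "MZ", "MZ", "GC"))
  scoped <- names(spec)[vapply(spec, function(s)
    identical(s$method, "kde") || identical(s$method, "gmm"), logical(1))]
  pieces <- list(); thrBy <- list()
  for (sc in unique(scopeCls)) {
    sel <- scopeCls == sc
    sub <- new("CellTable", cells = cc[sel, , drop = FALSE],
               provenance = cells@provenance)
    thr <- globalThr
    if (sum(sel) >= minScopeCells && length(scoped)) {
      local <- tryCatch(
        deriveThresholds(sub, spec[scoped], seed = deriveSeed(seed, sc)),
        error = function(e) NULL)
      if (!is.null(local)) {
        cuts <- thresholdCuts(globalThr)
        cuts[scoped] <- thresholdCuts(local)[scoped]
        thr <- new("ThresholdSet", cuts = cuts, method = globalThr@method,
                   parameters = spec)
      }
    }
    thrBy[[sc]] <- thr
    pieces[[sc]] <- cellData(applyGates(sub, panel$tree, thr))
  }
  out <- do.call(rbind, unname(pieces))
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  gated <- cells
  gated@cells <- out
  gated@provenance$gate_tree <- panel$tree@name
  gated@provenance$gate_paths <- gatePaths(panel$tree)
  gated@provenance$gate_parents <- vapply(panel$tree@nodes,
                                          function(n) n$parent, character(1))
  list(cells = gated, thresholds = list(global = globalThr,
                                        per_scope = thrBy))
}
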