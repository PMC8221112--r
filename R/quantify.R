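# Population quantification: relative frequencies and area-normalised
# densities over compartment scopes.

# Scope masks over an annotated event table. "F" is the whole follicle
# (MZ+LZ+DZ), "GC" the germinal centre (LZ+DZ), "Tzone" the CD4-dense
# extrafollicular space.
.scopeMask <- function(cc, scope) {
  if (!"region" %in% names(cc))
    stop("cells carry no compartment annotation; run assignCompartments first",
         call. = FALSE)
  switch(scope,
    all = rep(TRUE, nrow(cc)),
    EF = cc$region == "EF",
    MZ = cc$region == "MZ",
    LZ = cc$region == "LZ",
    DZ = cc$region == "DZ",
    F = cc$region %in% c("MZ", "LZ", "DZ"),
    GC = cc$region %in% c("LZ", "DZ"),
    Tzone = (cc$tzone %||% rep(FALSE, nrow(cc))) & cc$region == "EF",
    stop("unknown scope: ", scope, call. = FALSE))
}

.gateCol <- function(cc, population) {
  col <- paste0("gate_", population)
  if (!col %in% names(cc))
    stop("unknown population (no gate column): ", population, call. = FALSE)
  cc[[col]]
}

#' Quantify gated populations over compartment scopes
#'
#' Emits one row per requested (population, scope) combination with the
#' event count, the denominator, the relative frequency in percent and --
#' when a tissue area is supplied -- the area-normalised density in cells
#' per mm^2. Denominators: \code{"total"} (all cells in scope),
#' \code{"parent"} (the population's gate parent, in scope) or the name of
#' any gated population. A zero denominator yields a missing frequency,
#' never an error. Scope \code{"per-follicle"} emits one row per follicle
#' instance (cells with that follicle id).
#'
#' @param cells a gated, compartment-annotated \linkS4class{CellTable}.
#' @param spec data.frame (or list of lists) with columns/fields
#'   \code{population}, \code{scope}, \code{denominator}.
#' @param tissueAreaUm2 optional total tissue area for densities.
#' @return a data.frame (the quantification report).
#' @examples
#' # see the package vignette for an end-to-end example
#' @export
quantifyPopulations <- function(cells, spec, tissueAreaUm2 = NULL) {
  cc <- cellData(cells)
  if (is.data.frame(spec))
    spec <- lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ]))
  parents <- provenance(cells)$gate_parents
  rows <- list()
  for (rq in spec) {
    pop <- rq$population; scope <- rq$scope
    den <- rq$denominator %||% "total"
    inPop <- .gateCol(cc, pop)
    denomVec <- switch(den,
      total = rep(TRUE, nrow(cc)),
      parent = {
        p <- parents[[pop]]
        if (is.null(p) || identical(p, ""))
          rep(TRUE, nrow(cc)) else .gateCol(cc, p)
      },
      .gateCol(cc, den))
    if (identical(scope, "per-follicle")) {
      fids <- sort(unique(cc$follicle_id[cc$follicle_id > 0]))
      for (f in fids)
        rows[[length(rows) + 1L]] <- .quantRow(pop, scope, f,
          inPop & cc$follicle_id == f, denomVec & cc$follicle_id == f,
          den, tissueAreaUm2)
    } else {
      m <- .scopeMask(cc, scope)
      rows[[length(rows) + 1L]] <- .quantRow(pop, scope, NA_integer_,
        inPop & m, denomVec & m, den, tissueAreaUm2)
    }
  }
  do.call(rbind, rows)
}

.quantRow <- function(pop, scope, fid, num, den, denLabel, areaUm2) {
  count <- sum(num)
  nden <- sum(den)
  data.frame(
    population = pop, scope = scope, follicle_id = fid,
    denominator = denLabel, count = count, denominator_n = nden,
    frequency_pct = if (nden > 0) 100 * count / nden else NA_real_,
    density_per_mm2 = if (!is.null(areaUm2) && is.finite(areaUm2) &&
                          areaUm2 > 0) count / (areaUm2 / 1e6) else NA_real_,
    stringsAsFactors = FALSE)
}
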