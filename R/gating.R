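# Threshold derivation and hierarchical gating of the event table.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Derive lo/dim/hi thresholds per channel
#'
#' Supported methods, chosen per channel:
#' \describe{
#'   \item{gmm}{2- or 3-component univariate Gaussian mixture on log1p
#'     intensities (mclust, model "V"); cuts at the posterior-equality
#'     points between adjacent components ordered by mean. Suited to
#'     channels whose expression modes are all well represented.}
#'   \item{background}{single cut at \code{median + k * MAD} on the log1p
#'     scale. Suited to markers whose positive population is too rare for a
#'     mixture fit to be identifiable.}
#'   \item{background+gmm}{three levels: the lo cut from the background
#'     rule, then a 2-component mixture on the expressing subset for the
#'     dim/hi cut (e.g. PD-1, where the hi mode is rare overall but well
#'     represented among expressing cells).}
#'   \item{kde}{cuts at the density minima (valleys) between the dominant
#'     modes of the log1p distribution; \code{modes} widens the mode
#'     search beyond \code{levels}.}
#'   \item{cluster}{k-class 1D clustering on log1p intensities with cuts
#'     at the midpoints between adjacent class centres. For 2-level
#'     channels, \code{classes} > 2 adds low classes that absorb the
#'     neighbour-bleed bridge and \code{positive} picks how many top
#'     classes count as expressing.}
#'   \item{quantile}{cuts at the given probabilities.}
#'   \item{fixed}{cuts passed through verbatim.}
#' }
#'
#' @param cells a \linkS4class{CellTable} (>= \code{minCells} rows).
#' @param spec named list per channel:
#'   \code{list(method=, levels=, cuts=, probs=, k=, modes=, classes=,
#'   positive=)}; \code{levels} is 2 or 3, \code{cuts} is used by
#'   \code{fixed}, \code{probs} by \code{quantile}, \code{k} (default
#'   4.5) by the background rule, \code{modes} by \code{kde} and
#'   \code{classes}/\code{positive} by \code{cluster}.
#' @param minCells minimum number of events required.
#' @param seed seed for the mixture-model initialisation (mclust draws a
#'   random initialisation subset on large event tables); fixed so a given
#'   event table always yields the same cuts.
#' @return a \linkS4class{ThresholdSet}.
#' @export
deriveThresholds <- function(cells, spec, minCells = 50, seed = 1L) {
  withSeed(seed, .deriveThresholdsImpl(cells, spec, minCells))
}

.deriveThresholdsImpl <- function(cells, spec, minCells) {
  cc <- cellData(cells)
  if (nrow(cc) < minCells)
    stop(sprintf("threshold derivation needs >= %d cells (have %d)",
                 minCells, nrow(cc)), call. = FALSE)
  cuts <- list(); meth <- character(0)
  for (ch in names(spec)) {
    col <- paste0("mean_", ch)
    if (!col %in% names(cc))
      stop("channel not present in the event table: ", ch, call. = FALSE)
    s <- spec[[ch]]
    x <- cc[[col]]
    if (any(!is.finite(x)))
      stop("non-finite intensities in channel ", ch, call. = FALSE)
    cuts[[ch]] <- .deriveChannelCuts(x, s, ch)
    meth[ch] <- s$method
  }
  new("ThresholdSet", cuts = cuts, method = meth, parameters = spec)
}

.deriveChannelCuts <- function(x, s, ch) {
  method <- s$method %||% "gmm"
  levels <- s$levels %||% 2L
  if (method == "fixed") return(as.numeric(s$cuts))
  if (diff(range(x)) < 1e-12)
    stop(sprintf("channel '%s' is constant; use method='fixed'", ch),
         call. = FALSE)
  if (method == "quantile")
    return(as.numeric(quantile(x, s$probs, names = FALSE)))
  lx <- log1p(x)
  if (method == "background") {
    k <- s$k %||% 4.5
    return(expm1(median(lx) + k * mad(lx)))
  }
  if (method == "background+gmm") {
    k <- s$k %||% 4.5
    lo <- median(lx) + k * mad(lx)
    sub <- lx[lx > lo]
    hi <- if (length(sub) >= 30 && diff(range(sub)) > 1e-9)
      .gmmCuts(sub, 2L)[1] else as.numeric(quantile(sub, 0.5, names = FALSE))
    return(expm1(c(lo, hi)))
  }
  if (method == "cluster")
    return(expm1(.clusterCuts(lx, levels, classes = s$classes %||% levels,
                              positive = s$positive %||% (levels - 1L))))
  if (method == "gmm") return(expm1(.gmmCuts(lx, levels)))
  if (method == "kde")
    return(expm1(.kdeValleyCuts(lx, levels, searchModes = s$modes %||% levels)))
  stop("unknown threshold method: ", method, call. = FALSE)
}

# Clustering-based cuts on log1p intensities: `classes` 1D k-means classes
# are fitted and cuts are placed at midpoints between adjacent class
# centres. With classes > levels the extra low classes absorb the
# neighbour-bleed bridge between the negative and positive modes, and the
# returned cut separates the top `positive` classes from the rest -- the
# event-level analogue of gating above the bleed cloud in crowded tissue.
.clusterCuts <- function(lx, k, classes = k, positive = k - 1L) {
  classes <- max(classes, k)
  qs <- quantile(lx, seq(0.15, 0.92, length.out = classes), names = FALSE)
  if (diff(range(qs)) < 1e-9)
    stop("intensity distribution too narrow to cluster; use method='fixed'",
         call. = FALSE)
  km <- suppressWarnings(stats::kmeans(
    lx, centers = matrix(jitter(qs, amount = 1e-6)), iter.max = 100))
  ctr <- sort(km$centers[, 1])
  bounds <- vapply(seq_len(classes - 1L), function(i)
    (ctr[i] + ctr[i + 1L]) / 2, numeric(1))
  if (classes == k) return(bounds)
  if (k != 2L)
    stop("classes > levels is only supported for 2-level channels",
         call. = FALSE)
  bounds[classes - positive]
}

# Cutpoints at the density minima between the `k` dominant modes of the
# log1p intensity distribution. Robust to the "bridge" of intermediate
# values that neighbour-signal bleed-in creates between expression modes,
# since the valley sits where that bridge is thinnest. Falls back to
# mixture cuts when fewer than k separated modes exist.
.kdeValleyCuts <- function(lx, k, searchModes = k, minModeSep = 0.6) {
  searchModes <- max(searchModes, k)
  d <- stats::density(lx, bw = max(stats::bw.nrd0(lx), 0.15), n = 512)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmin <- which(diff(sign(diff(y))) == 2) + 1L
  sel <- integer(0)
  for (p in locmax[order(y[locmax], decreasing = TRUE)]) {
    if (all(abs(d$x[p] - d$x[sel]) > minModeSep)) sel <- c(sel, p)
    if (length(sel) == searchModes) break
  }
  if (length(sel) < k) return(.gmmCuts(lx, k))
  # cuts at the valleys between the k lowest-lying selected modes: with
  # searchModes > k this anchors the lo cut at the ambient/dim boundary
  # even when a brighter mode dominates
  sel <- sort(sel)[seq_len(k)]
  vapply(seq_len(k - 1L), function(i) {
    seg <- locmin[locmin > sel[i] & locmin < sel[i + 1L]]
    if (!length(seg)) (d$x[sel[i]] + d$x[sel[i + 1L]]) / 2
    else d$x[seg[which.min(y[seg])]]
  }, numeric(1))
}

# Posterior-equality cutpoints between adjacent mixture components
# (components ordered by mean); falls back to the midpoint when one
# component dominates the whole inter-mean interval.
.gmmCuts <- function(lx, G) {
  fit <- Mclust(lx, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit failed; consider method='fixed'", call. = FALSE)
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1L) sd <- rep(sd, G)
  pro <- fit$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sd <- sd[ord]; pro <- pro[ord]
  vapply(seq_len(G - 1L), function(i) {
    grid <- seq(mu[i], mu[i + 1L], length.out = 512)
    d <- log(pro[i]) + dnorm(grid, mu[i], sd[i], log = TRUE) -
      log(pro[i + 1L]) - dnorm(grid, mu[i + 1L], sd[i + 1L], log = TRUE)
    cross <- which(d[-length(d)] > 0 & d[-1] <= 0)
    if (length(cross)) grid[cross[1] + 1L] else (mu[i] + mu[i + 1L]) / 2
  }, numeric(1))
}

#' Construct a GateTree
#'
#' @param name panel/tree name.
#' @param nodes named list of nodes; each node is a list with
#'   \code{parent} (\code{""} for the root), optional \code{channels}
#'   (named character of levels among lo/dim/hi/+/-/"hi/dim") and optional
#'   \code{features} (list of \code{list(column, op, value)} terms, where
#'   \code{value} may be a number or \code{"median"}).
#' @return a \linkS4class{GateTree}.
#' @examples
#' tr <- gateTree("toy", list(
#'   all = list(parent = ""),
#'   B = list(parent = "all", channels = c(CD20 = "+"))))
#' gatePaths(tr)
#' @export
gateTree <- function(name, nodes) {
  nodes <- lapply(nodes, function(n) {
    n$parent <- n$parent %||% ""
    if (!is.null(n$channels)) n$channels <- unlist(n$channels)
    n
  })
  new("GateTree", name = name, nodes = nodes)
}

#' @rdname gateTree
#' @param tree a \linkS4class{GateTree}.
#' @return \code{gatePaths}: named character vector of "root/.../node"
#'   paths.
#' @export
gatePaths <- function(tree) {
  nd <- tree@nodes
  path <- function(nm) {
    p <- nd[[nm]]$parent
    if (identical(p, "")) nm else paste(path(p), nm, sep = "/")
  }
  setNames(vapply(names(nd), path, character(1)), names(nd))
}

# Assign each event a level per channel given its cutpoints.
# One cut: "-" below-or-equal, "+" above. Two cuts: lo/dim/hi with ties at
# a cutpoint going to the upper level.
.channelLevels <- function(x, cuts) {
  if (length(cuts) == 1L) ifelse(x > cuts, "hi", "lo")
  else ifelse(x > cuts[2], "hi", ifelse(x > cuts[1], "dim", "lo"))
}

.levelMatches <- function(levelVec, want, nCuts) {
  switch(want,
    "+" = levelVec != "lo",
    "hi/dim" = levelVec != "lo",
    "-" = levelVec == "lo",
    "lo" = levelVec == "lo",
    "dim" = levelVec == "dim",
    "hi" = levelVec == "hi",
    stop("invalid gate level: ", want, call. = FALSE))
}

#' Apply a hierarchical gate tree to an event table
#'
#' Annotates each cell with every gate node whose full ancestor predicate
#' chain it satisfies. Channel terms compare the cell's mean intensity to
#' the channel's cutpoints ("+" means above the (lo) cut; ties at a cut go
#' to the upper level); feature terms compare event-table columns (e.g.
#' \code{volume_um2 >= "median"}, the live-cell size filter).
#'
#' @param cells a \linkS4class{CellTable}.
#' @param tree a \linkS4class{GateTree}.
#' @param thresholds a \linkS4class{ThresholdSet} covering every channel the
#'   tree references.
#' @return the \linkS4class{CellTable} with one logical \code{gate_<node>}
#'   column per node; gate paths and parents are recorded in the
#'   provenance.
#' @export
applyGates <- function(cells, tree, thresholds) {
  cc <- cellData(cells)
  cuts <- thresholdCuts(thresholds)
  nd <- tree@nodes
  # resolve channel levels once
  used <- unique(unlist(lapply(nd, function(n) names(n$channels))))
  lev <- list()
  for (ch in used) {
    col <- paste0("mean_", ch)
    if (!col %in% names(cc))
      stop(sprintf("gate tree references channel '%s' absent from the event table", ch),
           call. = FALSE)
    if (is.null(cuts[[ch]]))
      stop(sprintf("no thresholds for channel '%s'", ch), call. = FALSE)
    lev[[ch]] <- .channelLevels(cc[[col]], cuts[[ch]])
  }
  memb <- list()
  evalNode <- function(nm) {
    if (!is.null(memb[[nm]])) return(memb[[nm]])
    n <- nd[[nm]]
    ok <- if (identical(n$parent, "")) rep(TRUE, nrow(cc)) else
      evalNode(n$parent)
    for (ch in names(n$channels))
      ok <- ok & .levelMatches(lev[[ch]], n$channels[[ch]],
                               length(cuts[[ch]]))
    for (ft in n$features) {
      if (!ft$column %in% names(cc))
        stop(sprintf("gate node '%s' references unknown feature '%s'",
                     nm, ft$column), call. = FALSE)
      v <- cc[[ft$column]]
      val <- if (identical(ft$value, "median")) median(v) else
        as.numeric(ft$value)
      ok <- ok & switch(ft$op,
                        ">=" = v >= val, ">" = v > val,
                        "<=" = v <= val, "<" = v < val,
                        stop("invalid feature op: ", ft$op, call. = FALSE))
    }
    memb[[nm]] <<- ok
    ok
  }
  for (nm in names(nd)) cc[[paste0("gate_", nm)]] <- evalNode(nm)
  out <- cells
  out@cells <- cc
  out@provenance$gate_tree <- tree@name
  out@provenance$gate_paths <- gatePaths(tree)
  out@provenance$gate_parents <- vapply(nd, function(n) n$parent,
                                        character(1))
  out
}
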