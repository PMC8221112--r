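# Spillover estimation from single-stain controls, linear compensation and
# autofluorescence subtraction.

#' Estimate a spillover matrix from single-stain control images
#'
#' For each fluorophore f, foreground pixels are those above the given
#' quantile of f's own channel. After subtracting each channel's background
#' (the median over non-foreground pixels), the mixing coefficient into
#' channel g is the robust slope of channel g on channel f over the
#' foreground: the median of per-pixel ratios (default) or the least-squares
#' slope. The diagonal is forced to 1 and negative estimates are clamped to
#' 0.
#'
#' @param singleStains named list of \linkS4class{MultichannelImage}, one per
#'   fluorophore, all sharing the same channel order (as produced by
#'   \code{\link{renderSingleStains}}).
#' @param foregroundQuantile quantile on the fluorophore's own channel above
#'   which pixels count as foreground.
#' @param minForeground minimum number of foreground pixels per fluorophore.
#' @param method \code{"median_ratio"} (robust, default) or
#'   \code{"least_squares"}.
#' @return a \linkS4class{SpilloverMatrix}.
#' @export
estimateSpillover <- function(singleStains, foregroundQuantile = 0.995,
                              minForeground = 100,
                              method = c("median_ratio", "least_squares")) {
  method <- match.arg(method)
  channels <- channelNames(singleStains[[1]])
  fl <- names(singleStains)
  if (!setequal(fl, channels))
    stop("single-stain names must match the image channel set", call. = FALSE)
  M <- diag(length(channels))
  dimnames(M) <- list(channels, channels)
  for (f in channels) {
    img <- singleStains[[f]]
    if (!identical(channelNames(img), channels))
      stop("inconsistent channel order across single stains", call. = FALSE)
    if (isStack(img)) img <- projectMIP(img)
    own <- as.numeric(getChannel(img, f))
    cut <- quantile(own, foregroundQuantile, names = FALSE)
    fg <- own > cut
    if (sum(fg) < minForeground)
      stop(sprintf("single stain '%s': only %d foreground pixels (need >= %d); is the image all background?",
                   f, sum(fg), minForeground), call. = FALSE)
    bgOwn <- median(own[!fg])
    xs <- own[fg] - bgOwn
    for (g in channels) {
      if (identical(g, f)) next
      other <- as.numeric(getChannel(img, g))
      ys <- other[fg] - median(other[!fg])
      slope <- if (method == "median_ratio") median(ys / xs)
               else sum(xs * ys) / sum(xs^2)
      M[f, g] <- min(1, max(0, slope))
    }
  }
  spilloverMatrix(M)
}

#' Apply spillover compensation
#'
#' Solves \code{observed = t(M) \%*\% true} per pixel and clamps negative
#' solutions to zero. The input image is left unmodified; the result is
#' flagged \code{compensated} in its metadata.
#'
#' @param image a \linkS4class{MultichannelImage}.
#' @param matrix a \linkS4class{SpilloverMatrix} whose channel order matches
#'   the image.
#' @return the compensated \linkS4class{MultichannelImage}.
#' @examples
#' m <- diag(2); dimnames(m) <- list(c("A","B"), c("A","B"))
#' img <- multichannelImage(array(1, c(4, 4, 2)), c("A","B"), 1)
#' identical(compensate(img, spilloverMatrix(m))@data, img@data)
#' @export
compensate <- function(image, matrix) {
  M <- spilloverCoefficients(matrix)
  if (!identical(channelNames(image), rownames(M)))
    stop("channel order of image and spillover matrix differ", call. = FALSE)
  d <- dim(image@data)
  nch <- d[length(d)]
  flat <- base::matrix(image@data, ncol = nch)
  truehat <- flat %*% solve(M)
  truehat[truehat < 0] <- 0
  out <- image
  out@data <- array(truehat, d)
  out@metadata$compensated <- TRUE
  out
}

#' Subtract a recorded autofluorescence channel
#'
#' Each target channel c becomes \code{max(0, c - coefficients[c] * AF)};
#' the autofluorescence channel itself is left unchanged.
#'
#' @param image a \linkS4class{MultichannelImage}.
#' @param afChannel name of the autofluorescence channel.
#' @param coefficients named non-negative scalars per target channel;
#'   channels not named are untouched.
#' @return the corrected \linkS4class{MultichannelImage}.
#' @export
subtractAutofluorescence <- function(image, afChannel, coefficients) {
  channels <- channelNames(image)
  if (!afChannel %in% channels)
    stop("unknown autofluorescence channel: ", afChannel, call. = FALSE)
  unknown <- setdiff(names(coefficients), channels)
  if (length(unknown))
    stop("unknown channel(s) in coefficients: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(coefficients < 0))
    stop("autofluorescence coefficients must be >= 0", call. = FALSE)
  out <- image
  af <- getChannel(image, afChannel)
  for (ch in setdiff(names(coefficients), afChannel)) {
    idx <- .channelIndex(image, ch)
    cur <- getChannel(image, ch)
    corrected <- pmax(0, cur - coefficients[[ch]] * af)
    if (isStack(image)) out@data[, , , idx] <- corrected
    else out@data[, , idx] <- corrected
  }
  out@metadata$af_subtracted <- afChannel
  out
}
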