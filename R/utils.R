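# Internal helpers: seeded RNG scoping, blurring, disk rasterisation.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministically derive a stage-specific seed (< 2^31) from a base seed.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483562) + 1L
}

# Gaussian blur of a matrix; sigma in micrometres. EBImage's FFT filter
# uses circular boundary handling, which is acceptable here because scenes
# keep a dark margin at the field edge.
gaussianBlur <- function(mat, sigmaUm, pixelSizeUm) {
  sigmaPx <- sigmaUm / pixelSizeUm
  if (sigmaPx <= 0) return(mat)
  r <- max(3, 2 * ceiling(3 * sigmaPx) + 1)
  r <- min(r, min(dim(mat)) - 1)
  if (r %% 2 == 0) r <- r - 1
  out <- EBImage::gblur(EBImage::Image(mat), sigma = sigmaPx, radius = r)
  matrix(as.numeric(out), nrow = nrow(mat))
}

# Linear pixel indices of a disk (annulus when rInner > 0) centred at
# (cy, cx) in pixel units, clipped to the H x W grid. Pixel centres are at
# index - 0.5 in this 1-based representation.
diskIndices <- function(H, W, cy, cx, r, rInner = 0) {
  ri <- ceiling(r + 0.5)
  y0 <- round(cy); x0 <- round(cx)
  ys <- max(1, y0 - ri):min(H, y0 + ri)
  xs <- max(1, x0 - ri):min(W, x0 + ri)
  if (!length(ys) || !length(xs)) return(integer(0))
  d2 <- outer((ys - 0.5 - cy)^2, (xs - 0.5 - cx)^2, "+")
  keep <- d2 <= r^2
  if (rInner > 0) keep <- keep & d2 > rInner^2
  idx <- which(keep)
  if (!length(idx)) return(integer(0))
  iy <- ((idx - 1) %% length(ys)) + 1
  ix <- ((idx - 1) %/% length(ys)) + 1
  (xs[ix] - 1) * H + ys[iy]
}

# Otsu threshold on raw values (histogram-based, 256 bins).
otsuThreshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1 + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sb <- (muT * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Log-normal draw parameterised by arithmetic mean and coefficient of
# variation; mean 0 yields exact zeros.
rlnormMeanCV <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Flatten a (y,x,channel) array into a (pixels x channels) matrix and back.
flattenChannels <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1] * d[2], ncol = d[3])
}

unflattenChannels <- function(mat, H, W) {
  array(mat, c(H, W, ncol(mat)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
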