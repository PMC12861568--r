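# Internal numerical helpers: FFT conventions, frequency grids, padding,
# small morphology. The package-wide transform convention is R's fft()
# (forward kernel exp(-2*pi*i*nu*x)); all frequencies are in cycles/nm.

ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT sample frequencies for n samples at spacing `px` nm (cycles/nm),
# in fft output order (DC first).
fft_freq <- function(n, px) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * px)
}

# |nu|^2 grid for an ny x nx field sampled at px nm.
freq_sq_grid <- function(ny, nx, px) {
  fy <- fft_freq(ny, px)
  fx <- fft_freq(nx, px)
  outer(fy^2, fx^2, "+")
}

# Replicate-pad a matrix by half its size on every side (2x per axis).
pad_replicate <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- c(rep(1L, ceiling(ny / 2)), seq_len(ny), rep(ny, floor(ny / 2)))
  ix <- c(rep(1L, ceiling(nx / 2)), seq_len(nx), rep(nx, floor(nx / 2)))
  m[iy, ix]
}

# Crop the central ny x nx region back out of a padded matrix.
crop_center <- function(m, ny, nx) {
  oy <- ceiling(ny / 2); ox <- ceiling(nx / 2)
  m[oy + seq_len(ny), ox + seq_len(nx)]
}

# Indices of the outermost `frac` frame of an ny x nx field (used to pin
# the unconstrained DC component of retrieved phase to the paraffin border).
border_frame_mask <- function(ny, nx, frac = 0.05) {
  by <- max(1L, ceiling(frac * ny)); bx <- max(1L, ceiling(frac * nx))
  m <- matrix(FALSE, ny, nx)
  m[c(seq_len(by), ny - seq_len(by) + 1L), ] <- TRUE
  m[, c(seq_len(bx), nx - seq_len(bx) + 1L)] <- TRUE
  m
}

# Binary erosion of a 3D mask by `n` steps of the 6-connected structuring
# element.
erode_mask <- function(mask, n = 1L) {
  d <- dim(mask)
  for (i in seq_len(n)) {
    out <- mask
    sh <- function(ax, by) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      src <- idx
      src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
      m <- mask[src[[1]], src[[2]], src[[3]]]
      # out-of-range neighbours count as background
      edge <- if (by > 0) d[ax] else 1L
      sel <- idx
      sel[[ax]] <- edge
      m[sel[[1]], sel[[2]], sel[[3]]] <- FALSE
      m
    }
    for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & sh(ax, by)
    mask <- out
  }
  mask
}

# Global Otsu threshold of a numeric array (maximises between-class
# variance on a fixed-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0)
    stop("Otsu threshold undefined: all values are equal")
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Gaussian smoothing of a 3D array (separable, reflective boundaries).
gaussian_smooth3d <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3)
  if (sigma <= 0) return(x)
  cpp_gauss3d(x, sigma)
}

# md5 of a file (manifest checksums)
file_md5 <- function(path) unname(tools::md5sum(path))

`%||%` <- function(a, b) if (is.null(a)) b else a
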