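# Tomographic reconstruction of retrieved phase maps: rotation-axis
# correction, 360->180 degree folding, and filtered back projection.
#
# Coordinate convention (shared with the projector): rotation about the
# central detector column, i.e. about coordinate (n-1)/2 in 0-based voxel
# units; linear interpolation throughout.

#' Find the rotation axis from opposing projections
#'
#' Cross-correlates the 0-degree projection with the horizontally mirrored
#' 180-degree projection over integer lags, refines the peak by quadratic
#' interpolation, and returns half the optimal lag: the subpixel offset of
#' the rotation axis from the central detector column.
#'
#' @param p0,p180 projection matrices (detector u x v) at 0 and 180 deg.
#' @param max_shift search half-range in pixels.
#' @return subpixel axis offset (detector pixels); 0 with a warning for
#'   featureless input, and a warning if the optimum sits at the edge of
#'   the search range.
#' @export
find_rotation_axis <- function(p0, p180, max_shift = 20L) {
  m180 <- p180[rev(seq_len(nrow(p180))), , drop = FALSE]
  # collapse to detector-column profiles (averages down per-pixel noise),
  # then correlate profile gradients: edges localize the optimum sharply
  # and smooth retrieval background drops out
  pa <- rowMeans(as.matrix(p0))
  pb <- rowMeans(as.matrix(m180))
  if (sd(pa) < 1e-12 || sd(pb) < 1e-12) {
    warning("featureless projections: rotation axis undetermined, returning 0")
    return(0)
  }
  # light identical smoothing of both profiles: suppresses pixel noise
  # without moving the correlation peak (shift theorem)
  k <- stats::dnorm(-6:6, sd = 2)
  k <- k / sum(k)
  pa <- as.numeric(stats::filter(pa, k, circular = TRUE))
  pb <- as.numeric(stats::filter(pb, k, circular = TRUE))
  a <- diff(pa); b <- diff(pb)
  lags <- -max_shift:max_shift
  score <- vapply(lags, function(l) {
    n <- length(a)
    ia <- max(1, 1 + l):min(n, n + l)
    ib <- ia - l
    sum(a[ia] * b[ib]) / sqrt(sum(a[ia]^2) * sum(b[ib]^2))
  }, numeric(1))
  k <- which.max(score)
  # only act on a clearly localized optimum: a flat-topped score profile
  # means the data cannot pin the axis at this noise level
  prominence <- max(score) - stats::quantile(score, 0.75, names = FALSE)
  if (prominence < 0.15) {
    warning("correlation peak not prominent: axis undetermined, returning 0")
    return(0)
  }
  if (k == 1L || k == length(lags))
    warning("correlation peak at the edge of the search range")
  lag <- lags[k]
  if (k > 1L && k < length(lags)) {
    y1 <- score[k - 1]; y2 <- score[k]; y3 <- score[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) lag <- lag + 0.5 * (y1 - y3) / denom
  }
  # sign convention: correcting the sinogram with shift_columns(., -offset)
  # (as fold_360() and fbp() do) re-centres the rotation axis
  -lag / 2
}

# shift sinogram columns by a subpixel amount (linear interpolation),
# replicating edges
shift_columns <- function(m, shift) {
  if (shift == 0) return(m)
  n <- nrow(m)
  x <- seq_len(n) + shift
  x0 <- pmin(pmax(floor(x), 1), n - 1)
  f <- pmin(pmax(x - x0, 0), 1)
  m[x0, , drop = FALSE] * (1 - f) + m[x0 + 1, , drop = FALSE] * f
}

#' Fold a 360-degree sinogram onto 180 degrees
#'
#' Each projection in the first half-turn is averaged with the horizontally
#' mirrored projection closest to its 180-degree partner (after optional
#' axis correction). With independent noise per half this halves the noise
#' variance.
#'
#' @param sinogram array `n_detector x n_angles x n_slices` (or a matrix
#'   for a single slice).
#' @param angles angles in degrees, strictly increasing, spanning 360 deg.
#' @param axis_offset subpixel axis offset to correct before folding.
#' @return list with `sinogram` (folded, `ceiling(n/2)` angles) and
#'   `angles`.
#' @export
fold_360 <- function(sinogram, angles, axis_offset = 0) {
  if (length(dim(sinogram)) == 2)
    dim(sinogram) <- c(dim(sinogram), 1L)
  stopifnot(all(diff(angles) > 0))
  na <- length(angles)
  span <- 360 - diff(angles)[1]
  if (angles[na] - angles[1] < span - 1e-9)
    stop("sinogram does not span 360 degrees")
  if (axis_offset != 0)
    for (z in seq_len(dim(sinogram)[3]))
      sinogram[, , z] <- shift_columns(sinogram[, , z], -axis_offset)
  keep <- seq_len(ceiling(na / 2))
  nu <- dim(sinogram)[1]
  mirrored <- sinogram[rev(seq_len(nu)), , , drop = FALSE]
  out <- sinogram[, keep, , drop = FALSE]
  mismatch <- 0
  for (i in keep) {
    target <- (angles[i] + 180) %% 360
    d <- (angles - target + 180) %% 360 - 180
    k <- which.min(abs(d))
    if (abs(d[k]) < 1e-9) {
      p <- mirrored[, k, , drop = FALSE]
    } else {
      # no exact partner: interpolate between the two bracketing angles
      mismatch <- max(mismatch, abs(d[k]))
      k2 <- if (d[k] > 0) (k - 2L) %% na + 1L else k %% na + 1L
      w <- abs(d[k2]) / (abs(d[k]) + abs(d[k2]))
      p <- w * mirrored[, k, , drop = FALSE] +
        (1 - w) * mirrored[, k2, , drop = FALSE]
    }
    out[, i, ] <- (out[, i, , drop = FALSE] + p) / 2
  }
  if (mismatch > 1e-6)
    warning(sprintf(
      "no exact 180-degree partners: interpolated pairing (max mismatch %.3g deg)",
      mismatch))
  list(sinogram = out, angles = angles[keep])
}

#' Convert a phase-map stack into per-slice sinograms
#'
#' @param phase array `n_u x n_v x n_angles` of phase maps (v = slice).
#' @return array `n_u x n_angles x n_v`.
#' @export
phase_to_sinograms <- function(phase) {
  aperm(phase, c(1, 3, 2))
}

# ramp filters on a zero-padded row length. The Ram-Lak response is the
# DFT of the band-limited ramp's impulse response (1/4 at 0, -1/(pi n)^2 at
# odd lags), which avoids the DC bias of sampling |f| directly; the other
# filters apply their window on top.
fbp_filter <- function(n_pad, filter) {
  k <- seq_len(n_pad) - 1
  k[k > n_pad / 2] <- k[k > n_pad / 2] - n_pad
  h <- numeric(n_pad)
  h[1] <- 0.25
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi * k[odd])^2
  ramp <- Re(stats::fft(h))
  f <- abs(fft_freq(n_pad, 1))  # cycles/sample, |f| <= 0.5
  w <- switch(filter,
    "ram-lak" = rep(1, n_pad),
    "shepp-logan" = {
      s <- rep(1, n_pad)
      nz <- f > 0
      s[nz] <- sin(pi * f[nz]) / (pi * f[nz])
      s
    },
    "hann" = 0.5 * (1 + cos(2 * pi * f)),
    stop("unknown filter: ", filter))
  ramp * w
}

#' Filtered back projection
#'
#' Standard parallel-beam FBP, slice by slice. The input sinograms are
#' phase line integrals (radians); the output is the per-voxel
#' refractive-index decrement delta, scaled so that forward projection of
#' the result reproduces the input phase:
#' `delta = FBP(phi) * lambda / (2 pi * voxel_size)`.
#' With `lambda = NULL` the sinogram is reconstructed in units of its own
#' line density per voxel length (useful when the input already is a delta
#' line integral in voxel units).
#'
#' @param sinograms array `n_detector x n_angles x n_slices` (or matrix).
#' @param angles angles in degrees.
#' @param filter `"ram-lak"` (default), `"shepp-logan"` or `"hann"`.
#' @param voxel_size voxel edge, nm.
#' @param lambda wavelength in nm (for phase input), or `NULL`.
#' @param axis_offset subpixel rotation-axis offset corrected before
#'   reconstruction.
#' @param nx output grid width in voxels (default: detector width; smaller
#'   values reconstruct the central region, e.g. when the detector is wider
#'   than the specimen).
#' @return object of class `tomogram`: 3D array of delta (dimensionless,
#'   relative to the embedding reference) with attributes.
#' @export
fbp <- function(sinograms, angles, filter = c("ram-lak", "shepp-logan",
                                              "hann"),
                voxel_size = 100, lambda = NULL, axis_offset = 0,
                nx = NULL) {
  filter <- match.arg(filter)
  if (length(dim(sinograms)) == 2)
    dim(sinograms) <- c(dim(sinograms), 1L)
  na <- length(angles)
  if (na < 3) stop("need at least 3 angles")
  d <- dim(sinograms)
  stopifnot(d[2] == na)
  if (axis_offset != 0)
    for (z in seq_len(d[3]))
      sinograms[, , z] <- shift_columns(sinograms[, , z], -axis_offset)
  nu <- d[1]
  n_pad <- 2^ceiling(log2(2 * nu))
  fw <- fbp_filter(n_pad, filter)
  filtered <- array(0, d)
  # filter all rows of all slices in one batched FFT
  flat <- matrix(0, n_pad, d[2] * d[3])
  flat[seq_len(nu), ] <- matrix(sinograms, nrow = nu)
  sp <- stats::mvfft(flat)
  sp <- sp * fw
  flat <- Re(stats::mvfft(sp, inverse = TRUE)) / n_pad
  filtered[] <- array(flat[seq_len(nu), ], d)
  nx <- nx %||% nu
  vol <- cpp_backproject(filtered, angles * pi / 180, nx, nx)
  vol <- vol * pi / na
  if (!is.null(lambda)) vol <- vol * lambda / (2 * pi * voxel_size)
  attr(vol, "voxel_size") <- voxel_size
  attr(vol, "filter") <- filter
  attr(vol, "n_angles") <- na
  attr(vol, "axis_offset") <- axis_offset
  class(vol) <- c("tomogram", class(vol))
  vol
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "tomogram: %d x %d x %d voxels at %g nm (%s filter, %d angles)\n",
    d[1], d[2], d[3], attr(x, "voxel_size"), attr(x, "filter"),
    attr(x, "n_angles")))
  invisible(x)
}
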