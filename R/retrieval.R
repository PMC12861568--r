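# Phase retrieval from flat-field-normalized holograms: multi-distance CTF
# (linearized), single-distance Paganin (homogeneous object), and nonlinear
# Tikhonov (NLT) refinement against the full propagation model, plus
# sinogram-domain ring suppression.
#
# Convention note. With T = exp(-B + i*phi) and the propagator used by
# fresnel_propagate(), the weak-contrast hologram spectrum is
#   F{I_j - 1}(nu) = -2 * (sin chi_j + cos(chi_j)/kappa) * phi_hat(nu),
#   chi_j = pi * lambda * z_j * |nu|^2,
# so the CTF estimator below uses F{1 - I_j} in the numerator and the
# Paganin filter carries a leading minus before its logarithm; both then
# return positive phase for objects denser than the embedding.

#' Phase-retrieval configuration
#'
#' @param method one of `"ctf"`, `"paganin"`, `"nlt"`.
#' @param kappa delta/beta ratio of the homogeneous-object model; `Inf`
#'   selects the pure-phase CTF.
#' @param alpha_low,alpha_high Tikhonov weights below/above the transition
#'   frequency (low frequencies are nearly in-band for multi-distance data,
#'   so `alpha_low` is small; high frequencies need stronger damping
#'   against noise).
#' @param nu_cut transition frequency in cycles/nm; `NULL` places it at the
#'   first CTF maximum of the shortest distance.
#' @param n_iter,step,penalty NLT iterations, initial step size and
#'   Tikhonov penalty weight.
#' @export
retrieval_config <- function(method = c("ctf", "paganin", "nlt"),
                             kappa = 500, alpha_low = 1e-5,
                             alpha_high = 1e-1, nu_cut = NULL,
                             n_iter = 15, step = 1, penalty = 1e-6) {
  method <- match.arg(method)
  stopifnot(alpha_low > 0, alpha_high > 0, n_iter >= 1)
  structure(list(method = method, kappa = kappa, alpha_low = alpha_low,
                 alpha_high = alpha_high, nu_cut = nu_cut,
                 n_iter = n_iter, step = step, penalty = penalty),
            class = "retrieval_config")
}

# chi_j = pi lambda z |nu|^2 on the padded grid
ctf_chi <- function(ny, nx, px, lambda, z) {
  pi * lambda * z * freq_sq_grid(ny, nx, px)
}

# two-band regularization alpha(nu) with a logistic blend at nu_cut
alpha_profile <- function(ny, nx, px, alpha_low, alpha_high, nu_cut) {
  nu <- sqrt(freq_sq_grid(ny, nx, px))
  w <- 1 / (1 + exp(-(nu - nu_cut) / (nu_cut / 10)))
  alpha_low + (alpha_high - alpha_low) * w
}

#' Multi-distance CTF phase retrieval
#'
#' Linearized (weak-contrast) Fourier-domain inversion of the contrast
#' transfer function over up to four propagation distances:
#' `phi_hat = sum_j s_j F{1 - I_j} / (2 sum_j s_j^2 + alpha(nu))` with
#' `s_j = sin(chi_j) + cos(chi_j)/kappa` (homogeneous object;
#' `kappa = Inf` gives the pure-phase CTF). The retrieved phase is relative:
#' its DC component is fixed by forcing the outermost 5 % border frame
#' (assumed paraffin) to zero mean.
#'
#' @param holograms list of normalized hologram matrices (or a 3D array
#'   `nu x nv x n_distances`), one per distance.
#' @param distances effective distances, nm (same length).
#' @param lambda wavelength, nm.
#' @param px_eff pixel size, nm.
#' @param config a [retrieval_config()].
#' @return phase map in radians (matrix), relative to the paraffin border.
#' @export
ctf_retrieve <- function(holograms, distances, lambda, px_eff,
                         config = retrieval_config()) {
  if (is.array(holograms) && length(dim(holograms)) == 3)
    holograms <- lapply(seq_len(dim(holograms)[3]),
                        function(j) holograms[, , j])
  if (!is.list(holograms)) holograms <- list(holograms)
  J <- length(holograms)
  stopifnot(J == length(distances))
  ny <- nrow(holograms[[1]]); nx <- ncol(holograms[[1]])
  py <- 2L * ny; pxn <- 2L * nx
  inv_kappa <- if (is.infinite(config$kappa)) 0 else 1 / config$kappa
  num <- matrix(0 + 0i, py, pxn)
  den <- matrix(0, py, pxn)
  for (j in seq_len(J)) {
    chi <- ctf_chi(py, pxn, px_eff, lambda, distances[j])
    s <- sin(chi) + inv_kappa * cos(chi)
    num <- num + s * stats::fft(pad_replicate(1 - holograms[[j]]))
    den <- den + s^2
  }
  if (J == 1 && inv_kappa == 0 && config$alpha_low < 1e-8)
    warning("single-distance pure-phase CTF has zero crossings in the band; results are ill-conditioned without regularization")
  nu_cut <- config$nu_cut %||% sqrt(1 / (2 * lambda * min(distances)))
  alpha <- alpha_profile(py, pxn, px_eff, config$alpha_low,
                         config$alpha_high, nu_cut)
  phi <- Re(ifft(num / (2 * den + alpha)))
  phi <- crop_center(phi, ny, nx)
  bm <- border_frame_mask(ny, nx)
  phi - mean(phi[bm])
}

#' Single-distance Paganin phase retrieval
#'
#' Homogeneous-object low-pass filter followed by a logarithm:
#' `phi = -(kappa/2) * ln( F^{-1}[ F{I} / (1 + pi lambda z kappa |nu|^2) ] )`.
#' Exact for a pure absorber at z = 0 and consistent with the CTF estimator
#' in the small-chi limit.
#'
#' @param hologram normalized hologram matrix.
#' @inheritParams ctf_retrieve
#' @param z_eff effective distance, nm.
#' @param kappa delta/beta ratio.
#' @return phase map in radians.
#' @export
paganin_retrieve <- function(hologram, lambda, z_eff, px_eff, kappa = 500) {
  ny <- nrow(hologram); nx <- ncol(hologram)
  p <- pad_replicate(hologram)
  den <- 1 + pi * lambda * z_eff * kappa *
    freq_sq_grid(nrow(p), ncol(p), px_eff)
  filt <- Re(ifft(stats::fft(p) / den))
  filt <- crop_center(filt, ny, nx)
  if (any(filt <= 0))
    stop("filtered intensity non-positive: logarithm undefined")
  -(kappa / 2) * log(filt)
}

#' Nonlinear Tikhonov (NLT) phase refinement
#'
#' Gradient descent with backtracking on the full (non-linearized)
#' propagation model,
#' `L(phi) = sum_j || |propagate(exp(-phi/kappa + i phi), z_j)|^2 - I_j ||^2
#'  + penalty * ||phi||^2`,
#' starting from a CTF or Paganin initialization. Propagation inside the
#' loss is periodic (no padding) so that the analytic gradient is the exact
#' adjoint.
#'
#' @param phi_init initial phase map (matrix).
#' @param holograms list (or 3D array) of normalized holograms.
#' @param distances effective distances, nm.
#' @param lambda,px_eff wavelength and pixel size, nm.
#' @param config a [retrieval_config()] (`kappa`, `n_iter`, `step`,
#'   `penalty` are used).
#' @return list with `phi` (refined map) and `loss` (non-increasing trace,
#'   element 1 = loss at the initialization).
#' @export
nlt_refine <- function(phi_init, holograms, distances, lambda, px_eff,
                       config = retrieval_config(method = "nlt")) {
  if (is.array(holograms) && length(dim(holograms)) == 3)
    holograms <- lapply(seq_len(dim(holograms)[3]),
                        function(j) holograms[, , j])
  obj <- nlt_objective(holograms, distances, lambda, px_eff,
                       config$kappa, config$penalty)
  phi <- phi_init
  loss <- obj$loss(phi)
  trace <- loss
  step <- config$step
  for (it in seq_len(config$n_iter)) {
    g <- obj$grad(phi)
    if (max(abs(g)) == 0) break   # exact stationary point
    ok <- FALSE
    for (bt in 1:30) {
      cand <- phi - step * g
      lc <- obj$loss(cand)
      if (lc < loss) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break   # stalled at machine precision: accept the iterate
    phi <- cand; loss <- lc
    trace <- c(trace, loss)
    step <- step * 2  # allow the step to grow back
  }
  list(phi = phi, loss = trace)
}

# closure bundling the NLT loss and its analytic gradient
nlt_objective <- function(holograms, distances, lambda, px_eff, kappa,
                          penalty) {
  cc <- complex(real = if (is.infinite(kappa)) 0 else -1 / kappa,
                imaginary = 1)
  forward <- function(phi) {
    Tf <- exp(cc * phi)
    lapply(distances, function(z)
      propagate_field(Tf, lambda, z, px_eff, pad = "none"))
  }
  loss <- function(phi) {
    ps <- forward(phi)
    s <- sum(vapply(seq_along(ps), function(j)
      sum((Mod(ps[[j]])^2 - holograms[[j]])^2), numeric(1)))
    s + penalty * sum(phi^2)
  }
  grad <- function(phi) {
    Tf <- exp(cc * phi)
    g <- matrix(0, nrow(phi), ncol(phi))
    for (j in seq_along(distances)) {
      psi <- propagate_field(Tf, lambda, distances[j], px_eff, pad = "none")
      r <- Mod(psi)^2 - holograms[[j]]
      back <- propagate_field(r * psi, lambda, -distances[j], px_eff,
                              pad = "none")
      g <- g + 4 * Re(Conj(cc * Tf) * back)
    }
    g + 2 * penalty * phi
  }
  list(loss = loss, grad = grad)
}

#' Flatten the background of a phase map
#'
#' Fits a low-order 2D polynomial to the phase over a mask of known empty
#' (paraffin) pixels and subtracts the fitted surface from the whole map.
#' Phase retrieval leaves the lowest spatial-frequency modes of each
#' projection poorly constrained (the CTF vanishes as nu -> 0), so
#' per-projection noise accumulates in smooth background modes; anchoring
#' them on the empty margin around the specimen removes this without
#' touching object frequencies.
#'
#' @param phi phase map (matrix).
#' @param mask logical matrix of empty-region pixels.
#' @param degree polynomial degree (0 = offset only, 1 = tilt, 2 = default).
#' @return flattened phase map.
#' @export
flatten_phase <- function(phi, mask, degree = 2L) {
  stopifnot(identical(dim(phi), dim(mask)), any(mask))
  u <- (row(phi) - nrow(phi) / 2) / nrow(phi)
  v <- (col(phi) - ncol(phi) / 2) / ncol(phi)
  X <- cbind(1, u[mask], v[mask])
  Xf <- cbind(1, as.numeric(u), as.numeric(v))
  if (degree >= 2) {
    X <- cbind(X, u[mask]^2, v[mask]^2, u[mask] * v[mask])
    Xf <- cbind(Xf, as.numeric(u)^2, as.numeric(v)^2,
                as.numeric(u) * as.numeric(v))
  }
  if (degree == 0) { X <- X[, 1, drop = FALSE]; Xf <- Xf[, 1, drop = FALSE] }
  cf <- qr.coef(qr(X), phi[mask])
  phi - matrix(Xf %*% cf, nrow(phi), ncol(phi))
}

#' Ring suppression on a sinogram
#'
#' Removes the angle-invariant component of a sinogram (the signature of
#' detector/wavefront fixed-pattern errors that reconstruct as rings). The
#' column-wise mean over angles is computed; columns flagged as outliers by
#' a moving-median comparison are replaced by the median before a local
#' quadratic (Savitzky-Golay) background fit, so the smooth estimate
#' follows genuine object structure - including its extrema - while the
#' narrow fixed-pattern residual is subtracted from every projection. On a
#' ring-free smooth sinogram the operation is a near-identity.
#'
#' @param sinogram matrix `n_detector x n_angles`, or a 3D array
#'   `n_detector x n_angles x n_slices` processed slice by slice.
#' @param window moving-median / background-fit width in detector pixels
#'   (odd).
#' @return corrected sinogram, same shape.
#' @export
remove_rings <- function(sinogram, window = 11L) {
  if (length(dim(sinogram)) == 3) {
    for (z in seq_len(dim(sinogram)[3]))
      sinogram[, , z] <- remove_rings(sinogram[, , z], window)
    return(sinogram)
  }
  cm <- rowMeans(sinogram)
  window <- min(window, length(cm))
  if (window %% 2 == 0) window <- window - 1L
  if (window < 5) return(sinogram)
  med <- stats::runmed(cm, k = window, endrule = "median")
  dev <- cm - med
  scale <- stats::mad(dev)
  if (scale == 0) scale <- stats::sd(dev)
  # outlier columns: large AND isolated deviations (genuine object extrema
  # deviate over several adjacent columns and are left alone)
  n <- length(cm)
  nb <- pmax(abs(c(0, dev[-n])), abs(c(dev[-1], 0)))
  flags <- scale > 0 & abs(dev) > 3 * scale & abs(dev) > 2 * nb
  despiked <- ifelse(flags, med, cm)
  smooth <- sg_smooth(despiked, window)
  sinogram - (cm - smooth)
}

# local polynomial (Savitzky-Golay, quartic) smoother with least-squares
# end frames; exact on smooth low-order structure
sg_smooth <- function(y, k, p = 4L) {
  n <- length(y)
  half <- (k - 1L) %/% 2L
  p <- min(p, k - 2L)
  x <- -half:half
  X <- outer(x, 0:p, "^")
  w <- (solve(crossprod(X)) %*% t(X))[1, ]   # central smoothing weights
  out <- as.numeric(stats::filter(y, rev(w), sides = 2))
  # end frames: one-sided local polynomial fit
  for (i in c(seq_len(half), (n - half + 1):n)) {
    idx <- max(1, i - half):min(n, i + half)
    Xi <- outer(idx - i, 0:min(p, length(idx) - 1L), "^")
    out[i] <- (Xi %*% qr.coef(qr(Xi), y[idx]))[which(idx == i)]
  }
  out
}
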