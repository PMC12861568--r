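# Forward optical model: electron density -> refractive index -> projected
# phase -> Fresnel-propagated holograms with flat field and shot noise.
#
# Geometry is always the equivalent parallel beam: cone-beam (zoom) setups
# are mapped onto it by the Fresnel scaling theorem (cone_to_parallel()),
# which is how divergent-beam holotomography is routinely processed.

#' X-ray wavelength from photon energy
#'
#' @param energy_keV photon energy in keV (the synchrotron configurations
#'   emulated here use 17.1 or 33.6 keV).
#' @return wavelength in nm (`hc/E` with `hc = 1.239842 eV um`).
#' @export
#' @examples
#' wavelength_from_energy(17.1)
wavelength_from_energy <- function(energy_keV) {
  if (any(energy_keV <= 0)) stop("photon energy must be positive")
  1.239842e-3 / energy_keV * 1e3 # 1.239842 eV.um = 1239.842 eV.nm
}

#' Electron density to refractive-index decrement
#'
#' The decrement of the x-ray refractive index n = 1 - delta + i*beta is
#' proportional to electron density: delta = r_e lambda^2 rho_e / (2 pi).
#'
#' @param rho_e electron density in e/nm^3 (may be an array).
#' @param lambda wavelength in nm.
#' @return delta, dimensionless, same shape as `rho_e`.
#' @seealso [delta_to_rho()] for the exact inverse.
#' @export
rho_to_delta <- function(rho_e, lambda) {
  .r_e * lambda^2 / (2 * pi) * rho_e
}

#' Absorption index under the homogeneous-object assumption
#'
#' @param delta refractive-index decrement.
#' @param kappa delta/beta ratio (dimensionless).
#' @export
beta_from_delta <- function(delta, kappa) delta / kappa

#' Fresnel number of a propagation configuration
#'
#' F = px_eff^2 / (lambda * z_eff). The holographic regime exploited by
#' propagation-based phase contrast corresponds to F << 1.
#'
#' @param px_eff effective pixel size, nm.
#' @param lambda wavelength, nm.
#' @param z_eff effective propagation distance, nm.
#' @export
fresnel_number <- function(px_eff, lambda, z_eff) px_eff^2 / (lambda * z_eff)

#' Cone-beam to equivalent parallel-beam geometry (Fresnel scaling theorem)
#'
#' A point-source hologram at source-sample distance `z1` and
#' sample-detector distance `z2` equals a parallel-beam hologram with
#' magnification M = (z1 + z2)/z1, effective distance z_eff = z1 z2/(z1+z2)
#' and demagnified pixel px_eff = detector_pixel / M.
#'
#' @param z1 source-sample distance, nm (`Inf` for parallel beam).
#' @param z2 sample-detector distance, nm.
#' @param detector_pixel physical detector pixel, nm.
#' @return list with `M`, `z_eff`, `px_eff`.
#' @export
cone_to_parallel <- function(z1, z2, detector_pixel) {
  if (any(z2 <= 0) || any(z1 <= 0)) stop("distances must be positive")
  if (is.infinite(z1))
    return(list(M = 1, z_eff = z2, px_eff = detector_pixel))
  M <- (z1 + z2) / z1
  list(M = M, z_eff = z1 * z2 / (z1 + z2), px_eff = detector_pixel / M)
}

#' Acquisition / optics configuration
#'
#' Holds the source, geometry and detector parameters of a simulated
#' multi-distance holographic scan in equivalent-parallel geometry.
#'
#' The default distances are chosen so that the zero crossings of the four
#' contrast transfer functions interleave (no common zeros within the band),
#' with Fresnel numbers of about 0.005-0.01, i.e. deep in the holographic
#' regime (all shipped defaults satisfy F < 0.05).
#'
#' @param energy_keV photon energy, keV.
#' @param kappa delta/beta ratio of the homogeneous-object model.
#' @param px_eff effective pixel size, nm (should match the phantom voxel).
#' @param distances effective propagation distances z_eff, nm (1 to 4).
#' @param n_angles number of projection angles over 360 degrees.
#' @param photons_per_pixel expected photon count per detector pixel in the
#'   flat beam; `Inf` or values <= 0 disable noise.
#' @param flat_field_amp amplitude of the random smooth (second-order
#'   polynomial) detector gain, as a fraction of unity; 0 disables it.
#' @param dark_rate expected dark counts per pixel.
#' @param n_flats number of flat/dark frames acquired per distance.
#' @param fov_margin detector margin in pixels added around the projected
#'   specimen on every side (the detector field of view is larger than the
#'   tissue punch, so Fresnel fringes stay on the detector and the frame
#'   border is clean paraffin).
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(energy_keV = 17.1,
                          kappa = 500,
                          px_eff = 100,
                          distances = 8e6 * c(1, 1.4, 4, 7),
                          n_angles = 181,
                          photons_per_pixel = 5000,
                          flat_field_amp = 0.05,
                          dark_rate = 50,
                          n_flats = 16,
                          fov_margin = 64) {
  stopifnot(energy_keV > 0, kappa > 0, px_eff > 0,
            length(distances) >= 1, length(distances) <= 4,
            all(distances > 0), n_angles >= 1)
  lambda <- wavelength_from_energy(energy_keV)
  fr <- fresnel_number(px_eff, lambda, distances)
  if (any(fr >= 1))
    warning("Fresnel number >= 1 at some distance: outside the holographic regime")
  structure(list(
    energy_keV = energy_keV, lambda = lambda, kappa = kappa,
    px_eff = px_eff, distances = distances, fresnel = fr,
    n_angles = n_angles, photons_per_pixel = photons_per_pixel,
    flat_field_amp = flat_field_amp, dark_rate = dark_rate,
    n_flats = n_flats, fov_margin = as.integer(fov_margin)
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf("optics_config: %.1f keV (lambda %.5f nm), kappa %g\n",
              x$energy_keV, x$lambda, x$kappa))
  cat(sprintf("  px_eff %g nm, %d angles over 360 deg, %g photons/px\n",
              x$px_eff, x$n_angles, x$photons_per_pixel))
  cat(sprintf("  distances (mm): %s | Fresnel numbers: %s\n",
              paste(signif(x$distances / 1e6, 3), collapse = ", "),
              paste(signif(x$fresnel, 3), collapse = ", ")))
  invisible(x)
}

#' Parallel-beam projection of an electron-density volume
#'
#' Computes the phase and absorption line integrals of one projection:
#' phi(u,v) = (2 pi / lambda) * integral of delta along the beam, with the
#' rotation about the vertical (third) volume axis and bilinear in-plane
#' interpolation; B = phi / kappa (homogeneous object).
#'
#' @param volume an [ed_volume()] or plain 3D array of electron density in
#'   e/nm^3.
#' @param angle projection angle in degrees.
#' @param optics an [optics_config()].
#' @param reference_rho electron density subtracted before projecting
#'   (0 returns absolute line integrals; the acquisition model uses the
#'   paraffin background so that contrast is relative to the embedding).
#' @return list with matrices `phi` (radians) and `B` (dimensionless),
#'   detector axes (u = rotated x, v = volume z).
#' @export
project_parallel <- function(volume, angle, optics, reference_rho = 0) {
  grid <- as_density_array(volume)
  vs <- attr(grid, "voxel_size") %||% optics$px_eff
  if (length(grid) == 0) stop("empty volume")
  delta <- rho_to_delta(grid - reference_rho, optics$lambda)
  proj <- cpp_project(delta, angle * pi / 180)
  phi <- (2 * pi / optics$lambda) * proj * vs
  list(phi = phi, B = phi / optics$kappa, angle = angle)
}

# internal: complex field propagation by the angular-spectrum Fresnel
# propagator exp(-i pi lambda z |nu|^2) (stated in the e^{+2 pi i nu x}
# transform convention; applied as its conjugate under R's fft kernel).
propagate_field <- function(Tfield, lambda, z_eff, px_eff,
                            pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  ny <- nrow(Tfield); nx <- ncol(Tfield)
  f <- if (pad == "replicate") pad_replicate(Tfield) else Tfield
  if (z_eff != 0) {
    H <- exp(1i * pi * lambda * z_eff *
               freq_sq_grid(nrow(f), ncol(f), px_eff))
    f <- ifft(stats::fft(f) * H)
  }
  if (pad == "replicate") f <- crop_center(f, ny, nx)
  f
}

#' Fresnel propagation of a complex transmission function
#'
#' Propagates T = exp(-B + i*phi) over an effective distance and returns
#' the hologram intensity I = |psi|^2. The field is replicate-padded to
#' twice its size before the transform to suppress wrap-around fringes
#' (disable with `pad = "none"`, which makes pure-phase propagation
#' conserve mean intensity exactly, by Parseval).
#'
#' @param Tfield complex matrix, the object transmission function.
#' @param lambda wavelength, nm.
#' @param z_eff effective propagation distance, nm (0 returns `|T|^2`).
#' @param px_eff pixel size, nm.
#' @param pad `"replicate"` (default) or `"none"`.
#' @return numeric matrix of intensities.
#' @export
fresnel_propagate <- function(Tfield, lambda, z_eff, px_eff,
                              pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  if (z_eff > 0 && fresnel_number(px_eff, lambda, z_eff) >= 1)
    warning("Fresnel number >= 1: outside the holographic regime")
  psi <- propagate_field(Tfield, lambda, z_eff, px_eff, pad)
  Mod(psi)^2
}

#' Simulate a multi-distance holographic tomography acquisition
#'
#' For every angle and distance: project the volume (contrast referenced to
#' the paraffin background), propagate, apply a smooth detector gain, scale
#' to the photon budget, Poisson-sample and add dark counts. Flat and dark
#' frames are simulated the same way and the returned stack is already
#' flat-field corrected via [flatfield_correct()].
#'
#' @param volume an [ed_volume()] (or 3D array) of electron density.
#' @param optics an [optics_config()].
#' @param seed integer seed; the acquisition is bit-reproducible.
#' @param reference_rho background electron density subtracted before the
#'   projection (defaults to the volume's `background_rho` attribute, or 0).
#' @param angles optional vector of angles in degrees (default: `n_angles`
#'   uniformly spaced over \[0, 360)).
#' @return an object of class `hologram_stack`: list with `intensities`
#'   (array `nu x nv x n_angles x n_distances`, flat-field normalized),
#'   `raw`, `flats`, `darks`, `angles`, `optics`.
#' @export
acquire <- function(volume, optics, seed = 1L,
                    reference_rho = NULL, angles = NULL) {
  grid <- as_density_array(volume)
  if (is.null(reference_rho))
    reference_rho <- attr(grid, "background_rho") %||% 0
  if (is.null(angles))
    angles <- seq(0, 360, length.out = optics$n_angles + 1)[seq_len(optics$n_angles)]
  m <- optics$fov_margin
  nu <- dim(grid)[1] + 2L * m; nv <- dim(grid)[3] + 2L * m
  nd <- length(optics$distances); na <- length(angles)
  noiseless <- array(0, c(nu, nv, na, nd))
  phi <- matrix(0, nu, nv)  # paraffin-referenced margin carries zero phase
  for (a in seq_len(na)) {
    pr <- project_parallel(grid, angles[a], optics, reference_rho)
    phi[m + seq_len(nrow(pr$phi)), m + seq_len(ncol(pr$phi))] <- pr$phi
    Tf <- exp(-phi / optics$kappa + 1i * phi)
    for (j in seq_len(nd))
      noiseless[, , a, j] <- fresnel_propagate(
        Tf, optics$lambda, optics$distances[j], optics$px_eff)
  }
  noisy <- optics$photons_per_pixel > 0 && is.finite(optics$photons_per_pixel)
  if (!noisy) {
    out <- list(intensities = noiseless, raw = noiseless,
                flats = NULL, darks = NULL,
                angles = angles, optics = optics, seed = seed,
                noiseless = TRUE)
    class(out) <- "hologram_stack"
    return(out)
  }
  set.seed(as.integer(seed))
  ph <- optics$photons_per_pixel
  gain <- array(1, c(nu, nv, nd))
  if (optics$flat_field_amp > 0)
    for (j in seq_len(nd)) gain[, , j] <- poly2_gain(nu, nv, optics$flat_field_amp)
  raw <- array(0, c(nu, nv, na, nd))
  for (j in seq_len(nd)) {
    lam <- sweep(noiseless[, , , j, drop = FALSE], c(1, 2),
                 gain[, , j] * ph, "*")
    raw[, , , j] <- stats::rpois(length(lam), lam) + optics$dark_rate
  }
  # rpois recycles the (nu,nv,nd) gain pattern over the n_flats frames
  flats <- array(stats::rpois(nu * nv * nd * optics$n_flats,
                              gain * ph) + optics$dark_rate,
                 c(nu, nv, nd, optics$n_flats))
  darks <- array(stats::rpois(nu * nv * optics$n_flats * nd,
                              optics$dark_rate),
                 c(nu, nv, nd, optics$n_flats))
  normalized <- flatfield_correct(raw, flats, darks)
  out <- list(intensities = normalized, raw = raw,
              flats = flats, darks = darks,
              angles = angles, optics = optics, seed = seed,
              noiseless = FALSE)
  class(out) <- "hologram_stack"
  out
}

# smooth random second-order 2D polynomial gain within +/- amp of unity
poly2_gain <- function(nu, nv, amp) {
  u <- seq(-1, 1, length.out = nu)
  v <- seq(-1, 1, length.out = nv)
  cf <- stats::runif(6, -1, 1)
  g <- cf[1] + cf[2] * outer(u, rep(1, nv)) + cf[3] * outer(rep(1, nu), v) +
    cf[4] * outer(u^2, rep(1, nv)) + cf[5] * outer(rep(1, nu), v^2) +
    cf[6] * outer(u, v)
  g <- g / max(abs(range(g)), 1e-12)
  1 + amp * g
}

#' Flat-field and dark-image correction
#'
#' Normalizes raw frames as (raw - dark) / (flat - dark), with flats and
#' darks averaged over their acquisition frames; negative results are
#' clipped to zero.
#'
#' @param raw array `nu x nv x n_angles x n_distances` of raw counts.
#' @param flats array `nu x nv x n_distances x n_flats` (or a single
#'   matrix) of flat frames.
#' @param darks like `flats`, dark frames (may be 0).
#' @return normalized intensity array shaped like `raw`.
#' @export
flatfield_correct <- function(raw, flats, darks = 0) {
  dr <- dim(raw)
  if (length(dr) == 2) { dim(raw) <- c(dr, 1, 1); dr <- dim(raw) }
  nd <- dr[4]
  avg_over_frames <- function(x, j) {
    if (length(x) == 1) return(matrix(x, dr[1], dr[2]))
    dx <- dim(x)
    if (length(dx) == 2) return(x)
    if (length(dx) == 4) return(apply(x[, , j, , drop = FALSE], c(1, 2), mean))
    x[, , j]
  }
  out <- array(0, dr)
  for (j in seq_len(nd)) {
    fl <- avg_over_frames(flats, j)
    dk <- avg_over_frames(darks, j)
    denom <- fl - dk
    if (any(denom <= 0)) stop("flat field not above dark level everywhere")
    sl <- sweep(sweep(raw[, , , j, drop = FALSE], c(1, 2), dk, "-"),
                c(1, 2), denom, "/")
    out[, , , j] <- pmax(sl, 0)
  }
  out
}

#' @export
print.hologram_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("hologram_stack: %d x %d detector, %d angles, %d distance(s)%s\n",
              d[1], d[2], d[3], d[4],
              if (isTRUE(x$noiseless)) " (noiseless)" else ""))
  invisible(x)
}
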