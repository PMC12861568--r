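# shared fixtures and oracles, built in code at test time

rel_l2 <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))

# analytic ball phantom: delta value inside a sphere, zero outside
ball_delta <- function(n, radius_vox, delta = 1e-6, center = (n + 1) / 2,
                       nz = n) {
  vol <- array(0, c(n, n, nz))
  ai <- arrayInd(seq_along(vol), dim(vol))
  czs <- if (nz == n) center else (nz + 1) / 2
  r2 <- (ai[, 1] - center)^2 + (ai[, 2] - center)^2 + (ai[, 3] - czs)^2
  vol[r2 <= radius_vox^2] <- delta
  vol
}

# ball as an electron-density volume (delta converted to rho at lambda)
ball_density <- function(n, radius_vox, delta = 1e-6, voxel_size = 100,
                         energy = 17.1, nz = n, center = (n + 1) / 2) {
  lambda <- wavelength_from_energy(energy)
  rho <- ball_delta(n, radius_vox, delta, center = center, nz = nz) *
    2 * pi / (xpct:::.r_e * lambda^2)
  ed_volume(rho, voxel_size)
}

# project a volume into per-slice sinograms of phase line integrals
phi_sinogram <- function(volume, angles, optics, reference_rho = 0) {
  d <- dim(volume)
  sino <- array(0, c(d[1], length(angles), d[3]))
  for (a in seq_along(angles))
    sino[, a, ] <- project_parallel(volume, angles[a], optics,
                                    reference_rho)$phi
  sino
}

# brute-force two-sided Mann-Whitney p by enumerating value assignments
# (independent of the package's midrank enumeration)
mw_brute_force_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Gaussian blob phase map for retrieval tests
blob_phase <- function(n = 128, amplitude = 0.1, sigma = 12) {
  x <- outer(seq_len(n) - (n + 1) / 2, rep(1, n))
  amplitude * exp(-(x^2 + t(x)^2) / (2 * sigma^2))
}

# tiny end-to-end run configuration used by pipeline tests (kept small so
# the suite stays fast; the acceptance tests exercise the full-size run)
tiny_run_config <- function(seed = 1L, outdir = tempfile("xpct_tiny_"),
                            noiseless = TRUE) {
  structures <- list(
    neuron(center = c(24, 24, 24), soma_radius = 1200,
           nucleus_center = c(24, 28, 24), nucleus_radius = 400,
           nucleolus_radius = 150),
    gvd(center = c(21, 19, 22), n_vacuoles = 3, vacuole_radius = 250,
        grain_radius = 100, region_radius = 700)
  )
  run_config(
    phantom = phantom_config(shape = c(48, 48, 48), voxel_size = 100,
                             structures = structures, seed = seed),
    optics = optics_config(
      distances = 5e6 * c(1, 1.7), n_angles = 48,
      photons_per_pixel = if (noiseless) Inf else 5000,
      flat_field_amp = if (noiseless) 0 else 0.05,
      fov_margin = 16),
    seed = seed, outdir = outdir)
}
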