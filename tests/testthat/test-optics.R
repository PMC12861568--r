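# Forward optics: wavelength, refractive index, geometry, projection,
# Fresnel propagation, acquisition and flat-field correction.

test_that("wavelength from energy matches hc/E", {
  expect_equal(wavelength_from_energy(17.1), 1239.842 / (17.1 * 1000),
               tolerance = 1e-12)
  expect_equal(wavelength_from_energy(17.1), 0.07251, tolerance = 1e-4)
  expect_equal(wavelength_from_energy(33.6), 0.03690, tolerance = 1e-4)
  expect_equal(wavelength_from_energy(17.1) / wavelength_from_energy(33.6),
               33.6 / 17.1, tolerance = 1e-12)
  expect_error(wavelength_from_energy(0), "positive")
})

test_that("rho <-> delta map is linear with the expected scale", {
  lambda <- wavelength_from_energy(17.1)
  expect_equal(rho_to_delta(328, lambda),
               2.8179403e-6 * lambda^2 * 328 / (2 * pi), tolerance = 1e-12)
  expect_equal(rho_to_delta(328, lambda), 7.73e-7, tolerance = 1e-3)
  expect_identical(rho_to_delta(0, lambda), 0)
  expect_equal(rho_to_delta(100, 2 * lambda) / rho_to_delta(100, lambda), 4)
  expect_equal(beta_from_delta(1e-6, 500), 2e-9)
})

test_that("Fresnel scaling theorem maps cone to parallel geometry", {
  p <- cone_to_parallel(Inf, 5e6, 100)
  expect_equal(p$M, 1)
  expect_equal(p$z_eff, 5e6)
  expect_equal(p$px_eff, 100)
  q <- cone_to_parallel(9e6, 991e6, 1e4)
  expect_equal(q$M, 1000 / 9, tolerance = 1e-12)
  expect_equal(q$px_eff, 90, tolerance = 1e-12)
  for (z1 in c(1e6, 3e7, 2e9)) {
    r <- cone_to_parallel(z1, 7e8, 1e4)
    expect_equal(r$M * r$px_eff, 1e4, tolerance = 1e-9)
  }
  expect_error(cone_to_parallel(-1, 1, 1), "positive")
})

test_that("projection of a uniform slab matches the closed form r_e lambda rho t", {
  # 1 mm paraffin path: 32 voxels of 31250 nm
  vol <- ed_volume(array(328, c(32, 32, 32)), voxel_size = 31250)
  opt <- suppressWarnings(optics_config(px_eff = 31250, distances = 5e6,
                                        photons_per_pixel = Inf))
  pr <- project_parallel(vol, 0, opt)
  phi_expect <- 2.8179403e-6 * opt$lambda * 328 * 1e6
  expect_equal(mean(pr$phi[16, ]), phi_expect, tolerance = 1e-6)
  expect_equal(phi_expect, 67, tolerance = 0.01)
  expect_equal(pr$B, pr$phi / opt$kappa)
})

test_that("projection is periodic in 360 degrees and linear in the volume", {
  vol <- ball_density(48, 12)
  opt <- optics_config(photons_per_pixel = Inf)
  p0 <- project_parallel(vol, 33, opt)$phi
  p360 <- project_parallel(vol, 393, opt)$phi
  expect_lt(max(abs(p0 - p360)), 1e-9 * max(abs(p0)))
  # linearity
  v2 <- ed_volume(2.5 * unclass(vol), 100)
  expect_equal(project_parallel(v2, 33, opt)$phi, 2.5 * p0,
               tolerance = 1e-9)
})

test_that("phase scales as 1/E between the two beamline energies", {
  vol <- ball_density(32, 8)
  o1 <- optics_config(energy_keV = 17.1, photons_per_pixel = Inf)
  o2 <- optics_config(energy_keV = 33.6, photons_per_pixel = Inf)
  p1 <- project_parallel(vol, 20, o1)$phi
  p2 <- project_parallel(vol, 20, o2)$phi
  expect_equal(p2, p1 * 17.1 / 33.6, tolerance = 1e-12)
})

test_that("Fresnel propagation: identity at z = 0 and unitary for pure phase", {
  phi <- blob_phase(64, 0.3, 5)
  Tf <- exp(1i * phi)
  I0 <- fresnel_propagate(Tf, 0.0725, 0, 100)
  expect_equal(I0, Mod(Tf)^2, tolerance = 1e-12)
  I1 <- fresnel_propagate(Tf, 0.0725, 5e6, 100, pad = "none")
  expect_lt(abs(mean(I1) - 1), 1e-12)
  I2 <- fresnel_propagate(Tf, 0.0725, 5e6, 100)
  expect_lt(abs(mean(I2) - 1), 1e-6)
  expect_warning(fresnel_propagate(Tf, 0.0725, 1e4, 100), "holographic")
})

test_that("single-voxel phase dot matches direct Fresnel quadrature", {
  n <- 128; px <- 100; lambda <- 0.0725
  z <- px^2 / (0.012 * lambda)  # F = 0.012
  Tf <- matrix(1 + 0i, n, n)
  i0 <- n / 2
  Tf[i0, i0] <- exp(0.5i)
  I_disc <- fresnel_propagate(Tf, lambda, z, px, pad = "none")
  # direct quadrature: scattered field = (T - 1) convolved with the
  # analytic Fresnel kernel h(x) = (i / (lambda z)) exp(-i pi |x|^2/(lambda z))
  xs <- (seq_len(n) - i0) * px
  r2 <- outer(xs^2, xs^2, "+")
  h <- (1i / (lambda * z)) * exp(-1i * pi * r2 / (lambda * z))
  psi <- 1 + (exp(0.5i) - 1) * h * px^2
  I_quad <- Mod(psi)^2
  ctr <- i0 + (-20:20)
  expect_lt(max(abs(I_disc[ctr, ctr] - I_quad[ctr, ctr])), 0.01)
})

test_that("acquire is deterministic, noise-free in the photon limit, and flat on paraffin", {
  vol <- ed_volume(array(328, c(32, 32, 32)), 100, 328)
  opt <- optics_config(distances = 5e6 * c(1, 1.7), n_angles = 4,
                       photons_per_pixel = Inf, fov_margin = 8)
  st <- acquire(vol, opt, seed = 1)
  expect_true(st$noiseless)
  expect_lt(max(abs(st$intensities - 1)), 1e-9)

  optn <- optics_config(distances = 5e6 * c(1, 1.7), n_angles = 4,
                        fov_margin = 8)
  a <- acquire(vol, optn, seed = 5)
  b <- acquire(vol, optn, seed = 5)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$raw, b$raw)
  # paraffin-only: normalized intensity approximately 1 +/- shot noise
  expect_lt(abs(mean(a$intensities) - 1), 0.005)
  expect_lt(sd(a$intensities), 2 / sqrt(5000))
})

test_that("flat-field correction inverts the detector gain", {
  raw <- array(runif(32 * 32 * 3, 0.5, 2), c(32, 32, 3, 1))
  flat <- matrix(1000, 32, 32)
  expect_equal(flatfield_correct(raw * 1000, flat, 0), raw,
               tolerance = 1e-12)
  expect_lt(max(abs(flatfield_correct(array(rep(flat, 3), dim(raw)),
                                      flat, 0) - 1)), 1e-12)
  # synthetic smooth gain injected then corrected
  set.seed(4)
  gain <- xpct:::poly2_gain(32, 32, 0.05)
  rawg <- sweep(raw, c(1, 2), gain * 1000, "*")
  corr <- flatfield_correct(rawg, gain * 1000, 0)
  expect_lt(max(abs(corr - raw) / raw), 0.005)
  expect_error(flatfield_correct(raw, matrix(0, 32, 32), 0), "flat")
})

test_that("shipped default configuration stays in the holographic regime", {
  opt <- optics_config()
  expect_true(all(opt$fresnel < 0.05))
  expect_true(all(opt$fresnel > 0))
})
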