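# Phase retrieval: CTF, Paganin, NLT and ring suppression.

make_holograms <- function(phi, distances, lambda = 0.07251, px = 100,
                           kappa = 500, pad = "replicate") {
  Tf <- exp(-phi / kappa + 1i * phi)
  lapply(distances, function(z) fresnel_propagate(Tf, lambda, z, px,
                                                  pad = pad))
}

test_that("all retrieval methods return zero phase for unit holograms", {
  I1 <- matrix(1, 64, 64)
  zs <- 5e6 * c(1, 1.4, 2, 2.8)
  phi <- ctf_retrieve(rep(list(I1), 4), zs, 0.07251, 100)
  expect_lt(max(abs(phi)), 1e-12)
  expect_lt(max(abs(paganin_retrieve(I1, 0.07251, 5e6, 100, 500))), 1e-12)
  res <- nlt_refine(matrix(0, 64, 64), rep(list(I1), 4), zs, 0.07251, 100,
                    retrieval_config(method = "nlt", n_iter = 2))
  expect_lt(max(abs(res$phi)), 1e-12)
})

test_that("multi-distance CTF recovers a weak-phase object below 5% error", {
  phi <- blob_phase(128, 0.1, 12)
  zs <- 5e6 * c(1, 1.4, 2, 2.8)
  holos <- make_holograms(phi, zs)
  ret <- ctf_retrieve(holos, zs, 0.07251, 100,
                      retrieval_config(alpha_low = 1e-5))
  expect_lt(rel_l2(ret, phi), 0.05)
})

test_that("CTF retrieval is linear in the hologram contrast", {
  phiA <- blob_phase(64, 0.05, 6)
  phiB <- 0.04 * sin(outer(seq_len(64), seq_len(64)) / 40)
  zs <- 5e6 * c(1, 2)
  Ia <- make_holograms(phiA, zs)
  Ib <- make_holograms(phiB, zs)
  Isum <- lapply(1:2, function(j) Ia[[j]] + Ib[[j]] - 1)
  cfg <- retrieval_config()
  lhs <- ctf_retrieve(Isum, zs, 0.07251, 100, cfg)
  rhs <- ctf_retrieve(Ia, zs, 0.07251, 100, cfg) +
    ctf_retrieve(Ib, zs, 0.07251, 100, cfg)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("Paganin agrees with single-distance CTF in the small-chi regime", {
  phi <- blob_phase(128, 0.1, 12)
  z <- 2e5   # chi stays below ~0.3 over the object band
  holo <- make_holograms(phi, z)[[1]]
  pag <- paganin_retrieve(holo, 0.07251, z, 100, 500)
  ctf1 <- ctf_retrieve(list(holo), z, 0.07251, 100,
                       retrieval_config(alpha_low = 1e-9,
                                        alpha_high = 1e-9))
  expect_lt(rel_l2(pag, ctf1), 0.05)
  expect_lt(rel_l2(pag, phi), 0.05)
})

test_that("doubling kappa doubles the Paganin phase in the weak-contrast small-chi limit", {
  phi <- blob_phase(128, 0.02, 14)
  z <- 2e4   # tiny distance: kappa*chi << 1 (outside the holographic regime)
  holo <- suppressWarnings(make_holograms(phi, z, kappa = 500))[[1]]
  p1 <- paganin_retrieve(holo, 0.07251, z, 100, 500)
  p2 <- paganin_retrieve(holo, 0.07251, z, 100, 1000)
  expect_equal(mean(p2) / mean(p1), 2, tolerance = 0.05)
})

test_that("Paganin rejects non-positive filtered intensities", {
  expect_error(paganin_retrieve(matrix(0, 32, 32), 0.07251, 5e6, 100, 500),
               "logarithm")
})

test_that("NLT analytic gradient matches central finite differences", {
  set.seed(8)
  phi <- matrix(0.2 * rnorm(16 * 16), 16, 16)
  phi0 <- matrix(0.1, 16, 16)
  zs <- c(3e5, 6e5)
  holos <- suppressWarnings(make_holograms(phi, zs, px = 400))
  obj <- xpct:::nlt_objective(holos, zs, 0.07251, 400, 500, 1e-6)
  g <- obj$grad(phi0)
  h <- 1e-6
  for (idx in c(1L, 77L, 200L, 256L)) {
    up <- phi0; up[idx] <- up[idx] + h
    dn <- phi0; dn[idx] <- dn[idx] - h
    fd <- (obj$loss(up) - obj$loss(dn)) / (2 * h)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
})

test_that("NLT is a near-fixed point at the truth and reduces misfit from a CTF start", {
  phi <- blob_phase(64, 1.0, 8)   # strong phase
  zs <- 5e6 * c(1, 1.4, 2, 2.8)
  # generate with the same (periodic) propagation model the NLT loss uses
  holos <- make_holograms(phi, zs, pad = "none")
  cfg <- retrieval_config(method = "nlt", n_iter = 10, penalty = 1e-8)

  res0 <- nlt_refine(phi, holos, zs, 0.07251, 100, cfg)
  expect_lt(rel_l2(res0$phi, phi), 0.01)
  expect_lt(res0$loss[1], 1e-8 * sum(phi^2) * 1.5)

  init <- ctf_retrieve(holos, zs, 0.07251, 100)
  res <- nlt_refine(init, holos, zs, 0.07251, 100, cfg)
  misfit <- function(p) {
    sum(vapply(seq_along(zs), function(j)
      sum((fresnel_propagate(exp((-1 / 500 + 1i) * p), 0.07251, zs[j], 100,
                             pad = "none") - holos[[j]])^2), numeric(1)))
  }
  expect_lt(misfit(res$phi), misfit(init))
  expect_true(all(diff(res$loss) <= 0))
})

test_that("ring suppression is a near-no-op on clean sinograms and kills column offsets", {
  # smooth (Gaussian-blob) object: projections carry no kinks the running
  # median could clip
  n <- 64
  lambda <- wavelength_from_energy(17.1)
  blob <- exp(-(outer((1:n - 32.5)^2, (1:n - 32.5)^2, "+")) / (2 * 8^2))
  rho <- array(blob * 2, c(n, n, 8)) # e/nm^3 above reference, per slice
  vol <- ed_volume(rho, 100)
  opt <- optics_config(photons_per_pixel = Inf)
  angles <- seq(0, 179, by = 3)
  sino <- phi_sinogram(vol, angles, opt)
  out <- remove_rings(sino)
  expect_lt(max(abs(out - sino)), 1e-3 * max(abs(sino)))
  const <- matrix(5, 64, 60)
  expect_lt(max(abs(remove_rings(const) - const)), 1e-12)

  # inject a fixed per-column offset; ring amplitude is measured on the
  # annulus the offending column maps to (radius |30 - 32.5| = 2.5 px)
  bad <- sino
  bad[30, , ] <- bad[30, , ] + 0.2 * max(sino)
  clean_rec <- fbp(sino, angles, voxel_size = 100, lambda = lambda)
  bad_rec <- fbp(bad, angles, voxel_size = 100, lambda = lambda)
  fix_rec <- fbp(remove_rings(bad), angles, voxel_size = 100,
                 lambda = lambda)
  r2 <- outer((1:n - 32.5)^2, (1:n - 32.5)^2, "+")
  annulus <- array(r2 >= 1.5^2 & r2 <= 3.5^2, dim(clean_rec))
  ring_amp <- function(rec) sqrt(mean((rec - clean_rec)[annulus]^2))
  expect_gt(ring_amp(bad_rec) / ring_amp(fix_rec), 20)
})

test_that("phase background flattening removes smooth surfaces exactly", {
  u <- outer(seq_len(64) - 32, rep(1, 64)) / 64
  v <- t(u)
  surface <- 0.3 + 0.5 * u - 0.2 * v + 0.4 * u^2 - 0.1 * u * v
  phi <- blob_phase(64, 0.1, 5)
  band <- matrix(TRUE, 64, 64)
  band[17:48, 17:48] <- FALSE
  phi[band] <- 0   # object strictly inside the band's hole
  flat <- flatten_phase(phi + surface, band)
  expect_equal(max(abs(flat - phi)), 0, tolerance = 1e-9)
})
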