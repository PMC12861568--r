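# Phantom synthesis: geometry, ground truth, determinism.

test_that("structure-free phantom is uniform paraffin with a one-row truth table", {
  cfg <- phantom_config(shape = c(32, 32, 32), background_rho = 328)
  ph <- make_phantom(cfg)
  expect_true(all(ph$density == 328))
  expect_true(all(ph$labels == 0L))
  expect_equal(nrow(ph$truth), 1L)
  expect_equal(ph$truth$mean_rho, 328)
  expect_equal(ph$truth$compartment, "background")
})

test_that("sphere voxelization matches the analytic volume within 2%", {
  cfg <- phantom_config(shape = c(64, 64, 64), voxel_size = 100,
                        structures = list(
                          neuron(center = c(32, 32, 32), soma_radius = 1000,
                                 nucleus_radius = 300,
                                 nucleolus_radius = 100)))
  ph <- make_phantom(cfg)
  # the whole soma (all three compartments) is a radius-10-voxel ball
  n_soma <- sum(ph$labels > 0)
  expect_lt(abs(n_soma - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.02)
})

test_that("k Lewy-body specs produce exactly k connected core components", {
  specs <- list(
    lewy_body(center = c(20, 20, 20), core_radius = 400, halo_radius = 700),
    lewy_body(center = c(44, 24, 40), core_radius = 400, halo_radius = 700),
    lewy_body(center = c(28, 44, 44), core_radius = 400, halo_radius = 700))
  ph <- make_phantom(phantom_config(shape = c(64, 64, 64),
                                    structures = specs))
  legend <- attr(ph$labels, "legend")
  core_ids <- legend$label[legend$compartment == "core"]
  mask <- array(ph$labels %in% core_ids, dim(ph$labels))
  comp <- xpct:::cpp_label3d(mask, 26L)
  expect_equal(max(comp), 3L)
})

test_that("identical config and seed give a bit-identical phantom", {
  cfg <- default_run_config(seed = 42)$phantom
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a$density, b$density)
  expect_identical(as.integer(a$labels), as.integer(b$labels))
  expect_identical(a$truth, b$truth)
})

test_that("background voxels equal background_rho exactly and flat compartments are flat", {
  ph <- make_phantom(default_run_config(seed = 3)$phantom)
  expect_true(all(ph$density[ph$labels == 0L] == 328))
  legend <- attr(ph$labels, "legend")
  hb <- legend$label[legend$class == "hirano_body"]
  expect_true(all(ph$density[ph$labels == hb] == 358))
  cyto <- legend$label[legend$compartment == "cytoplasm"]
  expect_true(all(ph$density[ph$labels == cyto] == 332))
})

test_that("Hirano body extends beyond its host soma", {
  ph <- make_phantom(default_run_config(seed = 1)$phantom)
  legend <- attr(ph$labels, "legend")
  hb <- legend$label[legend$class == "hirano_body"]
  soma_ids <- legend$label[legend$class == "neuron"]
  hb_idx <- arrayInd(which(ph$labels == hb), dim(ph$labels))
  # soma mask = all neuron compartments plus anything carved out of it
  soma_center <- c(80, 80, 88); soma_r <- 58
  d <- sqrt(colSums((t(hb_idx) - soma_center)^2))
  expect_true(any(d > soma_r))   # protrudes
  expect_true(any(d < soma_r))   # and is anchored inside
})

test_that("Lewy body geometry is validated and rim inclusions sit in the halo", {
  expect_error(lewy_body(c(10, 10, 10), core_radius = 800,
                         halo_radius = 500), "smaller")
  # degenerate case: no rim inclusions -> exactly core + halo labels
  ph <- make_phantom(phantom_config(
    shape = c(64, 64, 64),
    structures = list(lewy_body(c(32, 32, 32), core_radius = 1000,
                                halo_radius = 1800, rim_n = 0))))
  expect_setequal(attr(ph$labels, "legend")$compartment, c("halo", "core"))

  # 15-um body at 250-nm voxels spans 60 voxels; 2.5-um rim inclusions
  ph2 <- make_phantom(phantom_config(
    shape = c(96, 96, 96), voxel_size = 250,
    structures = list(lewy_body(c(48, 48, 48), core_radius = 4500,
                                halo_radius = 7500, rim_n = 6,
                                rim_diameter = 2500))))
  legend <- attr(ph2$labels, "legend")
  rim <- legend$label[legend$compartment == "rim"]
  comp <- xpct:::cpp_label3d(array(ph2$labels == rim, dim(ph2$labels)), 26L)
  expect_equal(max(comp), 6L)
  # none of the inclusions reaches the core
  rim_idx <- arrayInd(which(ph2$labels == rim), dim(ph2$labels))
  expect_true(all(sqrt(colSums((t(rim_idx) - 48)^2)) > 4500 / 250))
})

test_that("lewy body diameter-to-voxel arithmetic holds (15 um at 100 nm)", {
  ph <- make_phantom(phantom_config(
    shape = c(192, 192, 192),
    structures = list(lewy_body(c(96, 96, 96), core_radius = 4000,
                                halo_radius = 7500))))
  idx <- arrayInd(which(ph$labels > 0), dim(ph$labels))
  span <- max(idx[, 1]) - min(idx[, 1]) + 1
  expect_equal(span, 150, tolerance = 0.02)
})

test_that("GvD lumens at paraffin density are exactly background; 18 grains; gradient bounds", {
  cfg <- phantom_config(shape = c(64, 64, 64), structures = list(
    gvd(center = c(32, 32, 32), n_vacuoles = 18, vacuole_radius = 500,
        grain_radius = 200, region_radius = 2200)))
  ph <- make_phantom(cfg)
  legend <- attr(ph$labels, "legend")
  lum <- legend$label[legend$compartment == "lumen"]
  expect_true(all(ph$density[ph$labels == lum] == 328))
  grain <- legend$label[legend$compartment == "grain"]
  comp <- xpct:::cpp_label3d(array(ph$labels == grain, dim(ph$labels)), 26L)
  expect_equal(max(comp), 18L)

  cfg2 <- phantom_config(shape = c(64, 64, 64), structures = list(
    gvd(center = c(32, 32, 32), n_vacuoles = 5, vacuole_radius = 500,
        grain_radius = 200, region_radius = 2200, gradient = TRUE,
        rho_lumen = 328, rho_grain = 340)))
  ph2 <- make_phantom(cfg2)
  lum2 <- attr(ph2$labels, "legend")
  lum2 <- lum2$label[lum2$compartment == "lumen"]
  m <- mean(ph2$density[ph2$labels == lum2])
  expect_gt(m, 328)
  expect_lt(m, 340)
  expect_error(gvd(c(1, 1, 1), grain_radius = 600, vacuole_radius = 500),
               "smaller")
  expect_error(gvd(c(1, 1, 1), rho_lumen = 340, rho_grain = 330), "exceed")
})

test_that("truth_summary equals brute-force voxelwise averaging", {
  ph <- make_phantom(tiny_run_config(seed = 11)$phantom)
  tr <- truth_summary(ph$labels, ph$density)
  lv <- as.integer(ph$labels)
  for (i in seq_len(nrow(tr))) {
    sel <- lv == tr$label[i]
    expect_identical(tr$n_voxels[i], sum(sel))
    expect_equal(tr$mean_rho[i], mean(ph$density[sel]))
  }
  expect_error(truth_summary(ph$labels,
                             ed_volume(array(1, c(8, 8, 8)), 100)),
               "shape")
})

test_that("placement errors are raised for out-of-bounds structures", {
  expect_error(make_phantom(phantom_config(
    shape = c(32, 32, 32),
    structures = list(plaque(c(30, 16, 16), core_radius = 400,
                             shell_radius = 800)))),
    "placement error")
  expect_error(make_phantom(phantom_config(
    shape = c(48, 48, 48), overlap = "error",
    structures = list(
      plaque(c(24, 24, 24), core_radius = 400, shell_radius = 800),
      plaque(c(26, 24, 24), core_radius = 400, shell_radius = 800)))),
    "overlap")
})
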