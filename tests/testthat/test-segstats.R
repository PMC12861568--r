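# Segmentation (threshold, watershed) and the statistical toolkit.

test_that("Otsu thresholding separates a two-level volume and filters specks", {
  vol <- array(1, c(32, 32, 32))
  vol[10:20, 10:20, 10:20] <- 5
  vol <- vol + array(runif(length(vol), -0.1, 0.1), dim(vol))
  seg <- threshold_segment(vol, mode = "otsu")
  # any threshold between the two levels separates them; Otsu lands at the
  # first bin of the empty gap
  expect_gt(seg$threshold, 1.0)
  expect_lt(seg$threshold, 4.9)
  expect_equal(seg$n_components, 1L)
  expect_equal(seg$sizes, 11^3, tolerance = 0.02)

  speck <- array(0, c(24, 24, 24))
  speck[2:4, 2:4, 2:4] <- 1            # 27 voxels
  speck[10:20, 10:20, 10:20] <- 1
  seg2 <- threshold_segment(speck, mode = "fixed", threshold = 0.5,
                            min_size = 50)
  expect_equal(seg2$n_components, 1L)
  expect_error(threshold_segment(array(1, c(8, 8, 8)), mode = "otsu"),
               "equal")
})

test_that("seeded watershed separates blobs and splits shared basins", {
  # two well-separated Gaussian blobs
  g <- function(c1, c2, c3, s) {
    ai <- arrayInd(1:32^3, c(32, 32, 32))
    array(exp(-((ai[, 1] - c1)^2 + (ai[, 2] - c2)^2 + (ai[, 3] - c3)^2) /
                (2 * s^2)), c(32, 32, 32))
  }
  two <- g(10, 10, 16, 3) + g(24, 24, 16, 3)
  seg <- seeded_watershed_3d(two, h = 0.3, mask = two > 0.05)
  expect_equal(seg$n_components, 2L)

  # merged blobs sharing a basin are split by the watershed line
  merged <- g(13, 16, 16, 3) + g(22, 16, 16, 3)
  segm <- seeded_watershed_3d(merged, h = 0.05, mask = merged > 0.2)
  expect_equal(segm$n_components, 2L)
  lab <- segm$labels
  expect_true(lab[13, 16, 16] != lab[22, 16, 16])

  expect_warning(seeded_watershed_3d(array(0, c(16, 16, 16)), h = 1),
                 "no watershed seeds")
})

test_that("watershed label count is monotone non-increasing in h", {
  set.seed(12)
  vol <- xpct:::cpp_gauss3d(array(rnorm(40^3), c(40, 40, 40)), 2)
  counts <- vapply(c(0.01, 0.03, 0.1, 0.3, 1),
                   function(h) suppressWarnings(
                     seeded_watershed_3d(vol, h)$n_components),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed recovers the 18 GvD granules on a noiseless phantom", {
  ph <- make_phantom(phantom_config(shape = c(64, 64, 64), structures = list(
    gvd(center = c(32, 32, 32), n_vacuoles = 18, vacuole_radius = 500,
        grain_radius = 200, region_radius = 2200))))
  vol <- unclass(ph$density)
  seg <- seeded_watershed_3d(vol, h = 5, mask = vol > 330)
  expect_lte(abs(seg$n_components - 18L), 1)
})

test_that("threshold segmentation recovers the Hirano body with Dice > 0.8", {
  ph <- make_phantom(default_run_config(seed = 6)$phantom)
  set.seed(6)
  noisy <- unclass(ph$density) +
    array(rnorm(length(ph$density), 0, 2), dim(ph$density))
  # fixed threshold midway between the neuromelanin and Hirano densities
  seg <- threshold_segment(noisy, mode = "fixed", threshold = 355,
                           min_size = 100)
  legend <- attr(ph$labels, "legend")
  hb <- legend$label[legend$class == "hirano_body"]
  expect_gt(dice_coefficient(seg$labels > 0, ph$labels == hb), 0.8)
})

test_that("Mann-Whitney U: worked example, symmetry, and invariants", {
  t1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(t1$U, 0)
  expect_equal(t1$p.value, 1 / 3)
  expect_equal(t1$method, "exact")

  t2 <- mann_whitney_u(c(5, 6, 7), c(5, 6, 7))
  expect_equal(t2$p.value, 1)

  expect_error(mann_whitney_u(numeric(0), 1), "empty")

  set.seed(2)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:6, n1, replace = TRUE)   # heavy ties
    y <- sample(1:6, n2, replace = TRUE)
    tt <- mann_whitney_u(x, y)
    expect_gte(tt$U, 0)
    expect_lte(tt$U, n1 * n2)
    expect_gte(tt$p.value, 0)
    expect_lte(tt$p.value, 1)
  }
})

test_that("exact branch equals brute-force enumeration over assignments", {
  set.seed(7)
  for (rep in 1:15) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- round(rnorm(n1), 1)               # occasional ties
    y <- round(rnorm(n2, 0.5), 1)
    expect_equal(mann_whitney_u(x, y)$p.value, mw_brute_force_p(x, y))
  }
})

test_that("exact branch matches wilcox.test for untied samples", {
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    ours <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(45, 0.6)
  ours <- mann_whitney_u(x, y)
  expect_equal(ours$method, "normal_approx")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 4), 1)
  expect_equal(bonferroni_adjust(0.2, m = 1), 0.2)
  p <- c(0.001, 0.2, 0.9)
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_error(bonferroni_adjust(1.2), "pvals")
})

test_that("density_report: null case, power case, and row count", {
  set.seed(21)
  same <- list(a = rnorm(20), b = rnorm(20))
  rep0 <- density_report(same, plot = FALSE)
  expect_true(all(rep0$tests$p_adj > 0.05))

  shifted <- list(a = rnorm(20, 0, 1), b = rnorm(20, 10, 1),
                  c = rnorm(20, 20, 1))
  rep1 <- density_report(shifted, plot = FALSE)
  expect_true(all(rep1$tests$p_adj < 0.001))
  expect_equal(nrow(rep1$report), 3 + choose(3, 2))

  small <- list(a = rnorm(20), b = rnorm(2), c = rnorm(20))
  rep2 <- density_report(small, plot = FALSE)
  expect_equal(rep2$excluded, "b")
  expect_equal(nrow(rep2$tests), 1L)
})
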