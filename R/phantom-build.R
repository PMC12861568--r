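# Phantom assembly: voxelization of structure specs into density and label
# grids plus the exact ground-truth table.

#' Build a phantom from its configuration
#'
#' Voxelizes every structure specification in order into an electron-density grid and
#' an aligned integer label grid, then summarizes the exact ground truth.
#' Later structures overwrite earlier ones (except nuclear compartments,
#' which are protected) under the default overlap policy; with
#' `overlap = "error"` any collision aborts. Identical configuration and
#' seed give a bit-identical phantom.
#'
#' @param config a [phantom_config()].
#' @return list of class `phantom` with elements `density` (an `ed_volume`:
#'   3D array with `voxel_size` and `background_rho` attributes), `labels`
#'   (integer array with a `legend` data frame: label, structure, class,
#'   compartment), and `truth` (the [truth_summary()] table).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  st <- new.env(parent = emptyenv())
  st$density <- array(config$background_rho, shape)
  st$labels <- array(0L, shape)
  st$protected <- array(FALSE, shape)
  st$legend <- list()
  st$next_label <- 0L
  st$shape <- shape
  st$vs <- config$voxel_size
  st$overlap <- config$overlap
  for (i in seq_along(config$structures)) {
    sp <- config$structures[[i]]
    set.seed((config$seed + 1000003L * i) %% .Machine$integer.max)
    add_fun <- switch(sp$class,
      neuron = add_neuron, lewy_body = add_lewy_body,
      hirano_body = add_hirano_body, gvd = add_gvd, plaque = add_plaque,
      nmg_cluster = add_nmg_cluster, vessel = add_vessel,
      stop("unknown structure class: ", sp$class))
    add_fun(st, sp, structure_id = i)
  }
  legend <- if (length(st$legend)) do.call(rbind, st$legend) else
    data.frame(label = integer(0), structure = integer(0),
               class = character(0), compartment = character(0))
  labels <- st$labels
  attr(labels, "legend") <- legend
  class(labels) <- c("label_volume", class(labels))
  density <- ed_volume(st$density, config$voxel_size,
                       config$background_rho)
  out <- list(density = density, labels = labels,
              truth = truth_summary(labels, density), config = config)
  class(out) <- "phantom"
  out
}

#' Electron-density volume container
#'
#' @param grid 3D numeric array, e/nm^3 (all finite and non-negative).
#' @param voxel_size voxel edge, nm.
#' @param background_rho reference (paraffin) density, e/nm^3, optional.
#' @export
ed_volume <- function(grid, voxel_size, background_rho = NULL) {
  stopifnot(length(dim(grid)) == 3, voxel_size > 0)
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("electron density must be finite and non-negative")
  attr(grid, "voxel_size") <- voxel_size
  attr(grid, "background_rho") <- background_rho
  class(grid) <- c("ed_volume", class(grid))
  grid
}

# strip class but keep attributes, for arithmetic-heavy internals
as_density_array <- function(x) {
  if (inherits(x, "phantom")) x <- x$density
  if (inherits(x, "ed_volume")) {
    cls <- class(x)
    class(x) <- setdiff(cls, "ed_volume")
  }
  x
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("phantom: %d x %d x %d voxels at %g nm, background %g e/nm^3\n",
              d[1], d[2], d[3], attr(x$density, "voxel_size"),
              attr(x$density, "background_rho")))
  cat(sprintf("  %d structures, %d labelled compartments\n",
              length(x$config$structures), nrow(attr(x$labels, "legend"))))
  invisible(x)
}

# write a compartment into the state; values may be a scalar or a vector
# aligned with idx
paint <- function(st, idx, values, structure_id, class, compartment,
                  protect = FALSE) {
  if (st$overlap == "error" && any(st$labels[idx] != 0L))
    stop("overlapping structures (overlap policy 'error')")
  keep <- !st$protected[idx]
  idx <- idx[keep]
  if (length(values) > 1) values <- values[keep]
  st$next_label <- st$next_label + 1L
  lab <- st$next_label
  st$density[idx] <- values
  st$labels[idx] <- lab
  if (protect) st$protected[idx] <- TRUE
  st$legend[[lab]] <- data.frame(label = lab, structure = structure_id,
                                 class = class, compartment = compartment,
                                 stringsAsFactors = FALSE)
  invisible(lab)
}

nm2vox <- function(x, st) x / st$vs

add_neuron <- function(st, sp, structure_id) {
  rs <- nm2vox(sp$soma_radius, st)
  check_bounds(st$shape, sp$center, rs, "neuron soma")
  soma <- sphere_voxels(st$shape, sp$center, rs)
  paint(st, soma$idx, sp$densities$cytoplasm, structure_id,
        "neuron", "cytoplasm")
  ncen <- sp$nucleus_center %||% sp$center
  rn <- nm2vox(sp$nucleus_radius, st)
  if (sqrt(sum((ncen - sp$center)^2)) + rn > rs)
    stop("placement error: nucleus extends outside the soma")
  nuc <- sphere_voxels(st$shape, ncen, rn)
  paint(st, nuc$idx, sp$densities$nucleus, structure_id,
        "neuron", "nucleus", protect = TRUE)
  nol <- sphere_voxels(st$shape, ncen, nm2vox(sp$nucleolus_radius, st))
  # the nucleolus is painted before protection would block it: clear the
  # protection inside the nucleolus, then paint and re-protect
  st$protected[nol$idx] <- FALSE
  paint(st, nol$idx, sp$densities$nucleolus, structure_id,
        "neuron", "nucleolus", protect = TRUE)
}

add_lewy_body <- function(st, sp, structure_id) {
  rh <- nm2vox(sp$halo_radius, st)
  rc <- nm2vox(sp$core_radius, st)
  check_bounds(st$shape, sp$center, rh, "Lewy body")
  halo <- sphere_voxels(st$shape, sp$center, rh)
  paint(st, halo$idx[halo$d > rc], sp$densities$halo, structure_id,
        "lewy_body", "halo")
  core <- sphere_voxels(st$shape, sp$center, rc)
  paint(st, core$idx, sp$densities$core, structure_id, "lewy_body", "core")
  if (sp$rim_n > 0) {
    rr <- nm2vox(sp$rim_diameter / 2, st)
    ring <- rh - rr              # inclusions touch the outer halo surface
    pb <- perp_basis(runif_sphere())
    a0 <- stats::runif(1, 0, 2 * pi)
    idx <- integer(0)
    for (k in seq_len(sp$rim_n)) {
      a <- a0 + 2 * pi * (k - 1) / sp$rim_n
      cen <- sp$center + ring * (cos(a) * pb$e1 + sin(a) * pb$e2)
      idx <- c(idx, sphere_voxels(st$shape, cen, rr)$idx)
    }
    paint(st, unique(idx), sp$densities$rim, structure_id,
          "lewy_body", "rim")
  }
}

add_hirano_body <- function(st, sp, structure_id) {
  axis <- if (is.null(sp$orientation)) runif_sphere() else
    unit_vector(sp$orientation)
  hl <- nm2vox(sp$length / 2, st)
  r <- nm2vox(sp$radius, st)
  check_bounds(st$shape, sp$center, abs(axis) * hl + r, "Hirano body")
  cap <- capsule_voxels(st$shape, sp$center, axis, hl, r)
  paint(st, cap$idx, sp$densities$body, structure_id, "hirano_body", "body")
}

add_gvd <- function(st, sp, structure_id) {
  rv <- nm2vox(sp$vacuole_radius, st)
  rg <- nm2vox(sp$grain_radius, st)
  rreg <- nm2vox(sp$region_radius, st)
  check_bounds(st$shape, sp$center, rreg, "GvD region")
  centers <- place_spheres(sp$center, rreg - rv, rv, sp$n_vacuoles)
  lumen_idx <- integer(0); lumen_val <- numeric(0)
  grain_idx <- integer(0)
  for (k in seq_len(nrow(centers))) {
    v <- sphere_voxels(st$shape, centers[k, ], rv)
    inl <- v$d > rg
    li <- v$idx[inl]
    if (sp$gradient) {
      f <- pmin(1, (v$d[inl] - rg) / (rv - rg))
      lv <- sp$densities$grain +
        (sp$densities$lumen - sp$densities$grain) * f
    } else lv <- rep(sp$densities$lumen, length(li))
    lumen_idx <- c(lumen_idx, li); lumen_val <- c(lumen_val, lv)
    grain_idx <- c(grain_idx, v$idx[!inl])
  }
  paint(st, lumen_idx, lumen_val, structure_id, "gvd", "lumen")
  paint(st, grain_idx, sp$densities$grain, structure_id, "gvd", "grain")
}

# rejection sampling of n non-overlapping sphere centres inside a ball,
# with greedy restarts when a fill stalls
place_spheres <- function(center, placement_radius, r_vox, n,
                          max_tries = 5000L, restarts = 50L) {
  if (placement_radius <= 0)
    stop("placement error: region too small for the vacuoles")
  for (rs in seq_len(restarts)) {
    out <- matrix(NA_real_, n, 3)
    got <- 0L
    for (t in seq_len(max_tries)) {
      u <- runif_sphere() * placement_radius * stats::runif(1)^(1 / 3)
      cand <- center + u
      if (got > 0) {
        d2 <- colSums((t(out[seq_len(got), , drop = FALSE]) - cand)^2)
        if (any(d2 < (2.05 * r_vox)^2)) next
      }
      got <- got + 1L
      out[got, ] <- cand
      if (got == n) return(out)
    }
  }
  stop("placement error: could not place all vacuoles without overlap")
}

add_plaque <- function(st, sp, structure_id) {
  rs <- nm2vox(sp$shell_radius, st)
  rc <- nm2vox(sp$core_radius, st)
  check_bounds(st$shape, sp$center, rs, "plaque")
  shell <- sphere_voxels(st$shape, sp$center, rs)
  paint(st, shell$idx[shell$d > rc], sp$densities$shell, structure_id,
        "plaque", "shell")
  core <- sphere_voxels(st$shape, sp$center, rc)
  paint(st, core$idx, sp$densities$core, structure_id, "plaque", "core")
}

add_nmg_cluster <- function(st, sp, structure_id) {
  rg <- nm2vox(sp$granule_radius, st)
  rreg <- nm2vox(sp$region_radius, st)
  check_bounds(st$shape, sp$center, rreg, "neuromelanin cluster")
  idx <- integer(0)
  for (k in seq_len(sp$n_granules)) {
    u <- runif_sphere() * (rreg - rg) * stats::runif(1)^(1 / 3)
    idx <- c(idx, sphere_voxels(st$shape, sp$center + u, rg)$idx)
  }
  paint(st, unique(idx), sp$densities$granule, structure_id,
        "nmg_cluster", "granule")
}

add_vessel <- function(st, sp, structure_id) {
  axis <- unit_vector(sp$axis)
  hl <- nm2vox(sp$length / 2, st)
  r <- nm2vox(sp$radius, st)
  rw <- nm2vox(sp$radius - sp$wall_thickness, st)
  check_bounds(st$shape, sp$center, abs(axis) * hl + r, "vessel")
  # cylinder = capsule minus the cap extension along the axis: use a
  # capsule of half-length hl - r so total axial extent is the cylinder's
  outer_vox <- cylinder_voxels(st$shape, sp$center, axis, hl, r)
  inner_vox <- cylinder_voxels(st$shape, sp$center, axis, hl, rw)
  wall <- setdiff(outer_vox, inner_vox)
  paint(st, wall, sp$densities$wall, structure_id, "vessel", "wall")
  paint(st, inner_vox, sp$densities$lumen, structure_id, "vessel", "lumen")
}

cylinder_voxels <- function(shape, center, axis, hl_vox, r_vox) {
  ext <- hl_vox + r_vox
  lo <- pmax(1L, floor(center - ext))
  hi <- pmin(shape, ceiling(center + ext))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  px <- g$x - center[1]; py <- g$y - center[2]; pz <- g$z - center[3]
  t <- px * axis[1] + py * axis[2] + pz * axis[3]
  d2 <- (px - t * axis[1])^2 + (py - t * axis[2])^2 + (pz - t * axis[3])^2
  sel <- abs(t) <= hl_vox & d2 <= r_vox^2
  g$x[sel] + (g$y[sel] - 1L) * shape[1] + (g$z[sel] - 1L) * shape[1] * shape[2]
}

#' Ground-truth summary of a labelled density volume
#'
#' One row per labelled compartment (plus the paraffin background, label 0)
#' with voxel count, centroid and the exact mean density over the label
#' mask. Deterministic; computed by voxelwise averaging.
#'
#' @param labels integer label volume (with `legend` attribute, as produced
#'   by [make_phantom()]).
#' @param density matching `ed_volume` or 3D array.
#' @return data frame: label, class, compartment, n_voxels, centroid
#'   (voxel coordinates), mean_rho.
#' @export
truth_summary <- function(labels, density) {
  grid <- as_density_array(density)
  if (!identical(dim(grid), dim(labels)))
    stop("label and density grids have different shapes")
  legend <- attr(labels, "legend")
  lv <- as.integer(labels)
  ids <- sort(unique(lv))
  n <- tabulate(lv + 1L, nbins = max(ids) + 1L)[ids + 1L]
  sums <- vapply(ids, function(i) sum(grid[lv == i]), numeric(1))
  d <- dim(grid)
  coord <- arrayInd(seq_along(lv), d)
  cent <- t(vapply(ids, function(i)
    colMeans(coord[lv == i, , drop = FALSE]), numeric(3)))
  out <- data.frame(label = ids,
                    class = "paraffin", compartment = "background",
                    n_voxels = n,
                    cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
                    mean_rho = sums / n, stringsAsFactors = FALSE)
  if (!is.null(legend) && nrow(legend)) {
    m <- match(out$label, legend$label)
    hit <- !is.na(m)
    out$class[hit] <- legend$class[m[hit]]
    out$compartment[hit] <- legend$compartment[m[hit]]
    out$structure <- NA_integer_
    out$structure[hit] <- legend$structure[m[hit]]
  } else out$structure <- ifelse(out$label == 0, NA_integer_, out$label)
  out
}
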