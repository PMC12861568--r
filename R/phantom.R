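# Synthetic neuropathology phantoms: 3D electron-density volumes with exact
# per-compartment ground truth, emulating paraffin-embedded tissue punches.
#
# Conventions: positions ("center") are in voxel coordinates (1-based, may
# be fractional); all lengths (radii, lengths, diameters) are in nm;
# densities are electron densities in e/nm^3. Label 0 is the paraffin
# background. The shipped default densities are plausible relative values
# chosen to reproduce the qualitative ordering of inclusion densities
# (Hirano body > neuromelanin > Lewy-body core > halo > cytoplasm >
# plaque shell > GvD lumen = paraffin); apart from the paraffin reference
# (328 e/nm^3) and the neuronal cytoplasm elevation (+4 e/nm^3) they are
# placeholders, not measured values.

#' Phantom configuration
#'
#' @param shape voxels per axis (3 integers, each >= 32).
#' @param voxel_size voxel edge length in nm (default 100 nm, within the
#'   90-140 nm effective pixel range of the emulated zoom-tomography setup).
#' @param background_rho paraffin electron density, e/nm^3.
#' @param structures list of structure specifications, see e.g.
#'   [lewy_body()], [gvd()], [hirano_body()].
#' @param seed master seed; every structure uses its own deterministic
#'   substream derived from it.
#' @param overlap `"overwrite"` (later structures overwrite earlier labels,
#'   except protected nuclear compartments) or `"error"`.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(160, 160, 160), voxel_size = 100,
                           background_rho = 328, structures = list(),
                           seed = 1L, overlap = c("overwrite", "error")) {
  overlap <- match.arg(overlap)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 32),
            voxel_size > 0, background_rho > 0)
  for (s in structures)
    if (!inherits(s, "structure_spec"))
      stop("structures must be built with the structure constructors")
  structure(list(shape = shape, voxel_size = voxel_size,
                 background_rho = background_rho, structures = structures,
                 seed = as.integer(seed), overlap = overlap),
            class = "phantom_config")
}

new_structure_spec <- function(cls, ...) {
  sp <- list(class = cls, ...)
  if (!is.null(sp$densities) && any(unlist(sp$densities) < 0))
    stop("densities must be non-negative")
  structure(sp, class = "structure_spec")
}

#' Neuron soma with nucleus and nucleolus
#'
#' @param center soma centre, voxel coordinates.
#' @param soma_radius,nucleus_radius,nucleolus_radius radii in nm.
#' @param nucleus_center optional nucleus centre (defaults to the soma
#'   centre); the nucleolus is concentric with the nucleus.
#' @param rho_cyto,rho_nucleus,rho_nucleolus electron densities, e/nm^3.
#'   The default cytoplasm value is paraffin + 4 e/nm^3, the mean somatic
#'   elevation reported for CA1 neurons.
#' @export
neuron <- function(center, soma_radius = 5200, rho_cyto = 332,
                   nucleus_center = NULL, nucleus_radius = 1400,
                   rho_nucleus = 334, nucleolus_radius = 450,
                   rho_nucleolus = 344) {
  stopifnot(nucleus_radius < soma_radius, nucleolus_radius < nucleus_radius)
  new_structure_spec("neuron", center = center, soma_radius = soma_radius,
                     nucleus_center = nucleus_center,
                     nucleus_radius = nucleus_radius,
                     nucleolus_radius = nucleolus_radius,
                     densities = list(cytoplasm = rho_cyto,
                                      nucleus = rho_nucleus,
                                      nucleolus = rho_nucleolus))
}

#' Lewy body: dense core, less dense halo, optional hypodense rim inclusions
#'
#' A concentric double sphere (homogeneous dense core, fainter shell) with
#' optional small hypodense spherical inclusions in a circular arrangement
#' on the outer halo.
#'
#' @param center centre, voxel coordinates.
#' @param core_radius,halo_radius radii in nm (`core < halo`; the default
#'   total diameter of 5 um is at the small end of the 5-25 um range).
#' @param rho_core,rho_halo,rho_rim densities, e/nm^3.
#' @param rim_n number of rim inclusions (0 for a plain two-compartment
#'   body).
#' @param rim_diameter inclusion diameter, nm (2-3 um scale inhomogeneities;
#'   must fit inside the halo shell).
#' @export
lewy_body <- function(center, core_radius = 1500, halo_radius = 2500,
                      rho_core = 346, rho_halo = 338,
                      rim_n = 0, rim_diameter = 2500, rho_rim = 330) {
  if (core_radius >= halo_radius)
    stop("core_radius must be smaller than halo_radius")
  if (rim_n > 0 && halo_radius - rim_diameter < core_radius)
    stop("rim inclusions of this diameter do not fit inside the halo")
  new_structure_spec("lewy_body", center = center,
                     core_radius = core_radius, halo_radius = halo_radius,
                     rim_n = as.integer(rim_n), rim_diameter = rim_diameter,
                     densities = list(core = rho_core, halo = rho_halo,
                                      rim = rho_rim))
}

#' Hirano body: rod-shaped inclusion modelled as a capsule
#'
#' A cylinder with hemispherical caps; by construction it may extend beyond
#' the host soma ("beyond usual nerve cell borders"). If no orientation is
#' given, one is drawn uniformly on the sphere from the structure's seed
#' substream.
#'
#' @param center capsule centre, voxel coordinates.
#' @param length cylindrical section length, nm (total extent is
#'   `length + 2*radius`).
#' @param radius capsule radius, nm.
#' @param rho density, e/nm^3 (highest of the shipped profile).
#' @param orientation optional 3-vector axis direction.
#' @export
hirano_body <- function(center, length = 4000, radius = 600, rho = 358,
                        orientation = NULL) {
  stopifnot(length > 0, radius > 0)
  new_structure_spec("hirano_body", center = center, length = length,
                     radius = radius, orientation = orientation,
                     densities = list(body = rho))
}

#' Granulovacuolar degeneration: vacuoles with central dense grains
#'
#' `n_vacuoles` spherical vacuoles are placed without overlap inside a
#' spherical region around `center`; each carries a central grain. With
#' `gradient = TRUE` the lumen density rises linearly from `rho_lumen` at
#' the vacuole wall to `rho_grain` at the grain surface, emulating the
#' observed density gradient toward the grain; otherwise the lumen is flat
#' at `rho_lumen` (the default equals paraffin: vacuolar space is nearly
#' protein-free).
#'
#' @param center region centre, voxel coordinates.
#' @param n_vacuoles number of vacuoles (default 18).
#' @param vacuole_radius,grain_radius radii in nm (`grain < vacuole`).
#' @param rho_lumen,rho_grain densities, e/nm^3 (`grain > lumen`).
#' @param gradient logical, radial lumen gradient toward the grain.
#' @param region_radius placement region radius, nm.
#' @export
gvd <- function(center, n_vacuoles = 18, vacuole_radius = 600,
                grain_radius = 250, rho_lumen = 328, rho_grain = 340,
                gradient = FALSE, region_radius = 2500) {
  if (grain_radius >= vacuole_radius)
    stop("grain_radius must be smaller than vacuole_radius")
  if (rho_grain <= rho_lumen)
    stop("grain density must exceed lumen density")
  stopifnot(n_vacuoles >= 1)
  new_structure_spec("gvd", center = center,
                     n_vacuoles = as.integer(n_vacuoles),
                     vacuole_radius = vacuole_radius,
                     grain_radius = grain_radius, gradient = gradient,
                     region_radius = region_radius,
                     densities = list(lumen = rho_lumen, grain = rho_grain))
}

#' Cored beta-amyloid plaque: dense core with faint shell
#' @param center centre, voxel coordinates.
#' @param core_radius,shell_radius radii, nm.
#' @param rho_core,rho_shell densities, e/nm^3.
#' @export
plaque <- function(center, core_radius = 800, shell_radius = 1400,
                   rho_core = 342, rho_shell = 330) {
  stopifnot(core_radius < shell_radius)
  new_structure_spec("plaque", center = center, core_radius = core_radius,
                     shell_radius = shell_radius,
                     densities = list(core = rho_core, shell = rho_shell))
}

#' Neuromelanin granule cluster
#' @param center cluster centre, voxel coordinates.
#' @param n_granules number of granules.
#' @param granule_radius,region_radius radii, nm.
#' @param rho density, e/nm^3.
#' @export
nmg_cluster <- function(center, n_granules = 30, granule_radius = 250,
                        region_radius = 1100, rho = 352) {
  stopifnot(n_granules >= 1, granule_radius < region_radius)
  new_structure_spec("nmg_cluster", center = center,
                     n_granules = as.integer(n_granules),
                     granule_radius = granule_radius,
                     region_radius = region_radius,
                     densities = list(granule = rho))
}

#' Cylindrical vessel segment (wall plus paraffin-like lumen)
#' @param center centre, voxel coordinates.
#' @param radius outer radius, nm.
#' @param wall_thickness wall thickness, nm.
#' @param length cylinder length, nm.
#' @param axis 3-vector axis direction.
#' @param rho_wall,rho_lumen densities, e/nm^3.
#' @export
vessel <- function(center, radius = 700, wall_thickness = 300,
                   length = 7000, axis = c(0, 1, 0),
                   rho_wall = 336, rho_lumen = 328) {
  stopifnot(wall_thickness < radius, length > 0)
  new_structure_spec("vessel", center = center, radius = radius,
                     wall_thickness = wall_thickness, length = length,
                     axis = axis,
                     densities = list(wall = rho_wall, lumen = rho_lumen))
}

# ---------------------------------------------------------------------------
# geometry helpers (voxel units)

# linear indices and center distances (voxels) of a ball
sphere_voxels <- function(shape, center, r_vox) {
  lo <- pmax(1L, floor(center - r_vox))
  hi <- pmin(shape, ceiling(center + r_vox))
  if (any(lo > hi)) return(list(idx = integer(0), d = numeric(0)))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center[1])^2; dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  sel <- which(d2 <= r_vox^2)
  if (length(sel) == 0) return(list(idx = integer(0), d = numeric(0)))
  ai <- arrayInd(sel, dim(d2))
  idx <- (xs[ai[, 1]]) +
    (ys[ai[, 2]] - 1L) * shape[1] +
    (zs[ai[, 3]] - 1L) * shape[1] * shape[2]
  list(idx = idx, d = sqrt(d2[sel]))
}

# linear indices and axial/radial distances of a capsule (segment +- hl
# along unit axis, radius r), all in voxels
capsule_voxels <- function(shape, center, axis, hl_vox, r_vox) {
  ext <- hl_vox + r_vox
  lo <- pmax(1L, floor(center - ext))
  hi <- pmin(shape, ceiling(center + ext))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  px <- g$x - center[1]; py <- g$y - center[2]; pz <- g$z - center[3]
  t <- px * axis[1] + py * axis[2] + pz * axis[3]
  tc <- pmin(pmax(t, -hl_vox), hl_vox)
  d2 <- (px - tc * axis[1])^2 + (py - tc * axis[2])^2 + (pz - tc * axis[3])^2
  sel <- d2 <= r_vox^2
  idx <- g$x[sel] + (g$y[sel] - 1L) * shape[1] +
    (g$z[sel] - 1L) * shape[1] * shape[2]
  list(idx = idx)
}

# true extreme coordinates (voxels) of a geometric primitive, for bounds
# checking before any voxel is written
check_bounds <- function(shape, center, extent_vox, what) {
  if (any(center - extent_vox < 1) || any(center + extent_vox > shape))
    stop(sprintf("placement error: %s extends outside the volume", what))
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length orientation")
  v / n
}

# random unit vector, uniform on the sphere
runif_sphere <- function() {
  z <- stats::runif(1, -1, 1)
  a <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(a), r * sin(a), z)
}

# orthonormal basis perpendicular to unit vector n
perp_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(cross3(n, ref))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
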