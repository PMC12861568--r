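# Artifact persistence: volumes and image stacks as 32-bit multi-page TIFF
# with JSON sidecars, tables as CSV. TIFF samples are stored scaled to
# [0, 1] (the affine transform is recorded in the sidecar), giving a
# round-trip precision of (max - min) / 2^32.

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  jp <- paste0(path, ".json")
  if (!file.exists(jp)) stop("missing JSON sidecar: ", jp)
  jsonlite::read_json(jp, simplifyVector = TRUE)
}

# scale an array to [0,1]; returns list(data, offset, scale) with
# value = offset + scale * stored
tiff_scale <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r))) stop("volume contains non-finite values")
  scale <- if (diff(r) > 0) diff(r) else 1
  list(data = (x - r[1]) / scale, offset = r[1], scale = scale)
}

#' Write a 3D volume as multi-page TIFF plus JSON sidecar
#'
#' @param volume 3D array (z slices become TIFF pages).
#' @param path output path without extension (writes `path.tif` and
#'   `path.json`).
#' @param voxel_size voxel edge, nm (defaults to the volume's attribute).
#' @param meta named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = NULL, meta = list()) {
  grid <- as_density_array(volume)
  stopifnot(length(dim(grid)) == 3)
  voxel_size <- voxel_size %||% attr(grid, "voxel_size")
  if (is.null(voxel_size)) stop("voxel_size required")
  sc <- tiff_scale(unclass(grid))
  pages <- lapply(seq_len(dim(grid)[3]), function(z) sc$data[, , z])
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  write_sidecar(path, c(list(dim = dim(grid), voxel_size = voxel_size,
                             offset = sc$offset, scale = sc$scale,
                             format = "xpct-volume-1"), meta))
  invisible(path)
}

#' Read a volume written by `write_volume()`
#'
#' @param path path without extension.
#' @return 3D array with `voxel_size` attribute and a `meta` attribute
#'   holding the sidecar contents.
#' @export
read_volume <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta$voxel_size)) stop("sidecar lacks voxel_size")
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  x <- array(0, meta$dim)
  for (z in seq_along(pages)) x[, , z] <- pages[[z]]
  x <- meta$offset + meta$scale * x
  attr(x, "voxel_size") <- meta$voxel_size
  attr(x, "meta") <- meta
  x
}

#' Write a hologram or phase-map stack (one TIFF per distance)
#'
#' Angles become TIFF pages; for 4D stacks a `_d<j>` suffix is appended per
#' distance. The sidecar records angles, distances, energy, pixel size,
#' Fresnel numbers and seed.
#'
#' @param stack a `hologram_stack`, or a 3D array `nu x nv x n_angles`
#'   (single distance), or 4D `nu x nv x n_angles x n_distances`.
#' @param path path without extension.
#' @param meta extra sidecar entries (required when `stack` is a bare
#'   array: supply at least `angles`).
#' @export
write_stack <- function(stack, path, meta = list()) {
  if (inherits(stack, "hologram_stack")) {
    o <- stack$optics
    meta <- c(list(angles = stack$angles, distances = o$distances,
                   energy_keV = o$energy_keV, px_eff = o$px_eff,
                   fresnel = o$fresnel, seed = stack$seed), meta)
    arr <- stack$intensities
  } else arr <- stack
  d <- dim(arr)
  if (length(d) == 3) { dim(arr) <- c(d, 1L); d <- dim(arr) }
  sc <- tiff_scale(arr)
  for (j in seq_len(d[4])) {
    pages <- lapply(seq_len(d[3]), function(a) sc$data[, , a, j])
    suffix <- if (d[4] > 1) sprintf("_d%d", j) else ""
    tiff::writeTIFF(pages, paste0(path, suffix, ".tif"),
                    bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  }
  write_sidecar(path, c(list(dim = d, offset = sc$offset, scale = sc$scale,
                             format = "xpct-stack-1"), meta))
  invisible(path)
}

#' Read a stack written by `write_stack()`
#' @param path path without extension.
#' @return 4D array with a `meta` attribute.
#' @export
read_stack <- function(path) {
  meta <- read_sidecar(path)
  d <- meta$dim
  arr <- array(0, d)
  for (j in seq_len(d[4])) {
    suffix <- if (d[4] > 1) sprintf("_d%d", j) else ""
    pages <- tiff::readTIFF(paste0(path, suffix, ".tif"), all = TRUE)
    for (a in seq_len(d[3])) arr[, , a, j] <- pages[[a]]
  }
  arr <- meta$offset + meta$scale * arr
  attr(arr, "meta") <- meta
  arr
}

#' Write/read a table as CSV (row order preserved)
#' @param x data frame.
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
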