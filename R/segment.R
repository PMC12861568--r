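# Automated segmentation of inclusions in reconstructed volumes:
# thresholding with connected components, and 3D seeded watershed with
# h-maxima seeds.

#' Threshold segmentation with connected components
#'
#' Binarizes a volume (global Otsu threshold or a fixed value), labels
#' 26-connected components and removes those below `min_size`.
#'
#' @param volume 3D numeric array.
#' @param mode `"otsu"` or `"fixed"`.
#' @param threshold threshold value for `mode = "fixed"`.
#' @param min_size minimum component size in voxels.
#' @return object of class `segmentation`: list with `labels` (integer
#'   array, consecutive labels), `threshold`, `sizes`, `centroids`,
#'   `method`.
#' @export
threshold_segment <- function(volume, mode = c("otsu", "fixed"),
                              threshold = NULL, min_size = 0L) {
  mode <- match.arg(mode)
  volume <- as_density_array(volume)
  if (any(!is.finite(volume))) stop("volume must be finite")
  thr <- switch(mode,
                otsu = otsu_threshold(volume),
                fixed = {
                  if (is.null(threshold)) stop("fixed mode needs a threshold")
                  threshold
                })
  lab <- cpp_label3d(array(volume > thr, dim(volume)), 26L)
  lab <- filter_relabel(lab, min_size)
  new_segmentation(lab, threshold = thr,
                   method = list(type = "threshold", mode = mode,
                                 min_size = min_size))
}

# drop components below min_size and relabel consecutively
filter_relabel <- function(lab, min_size) {
  sizes <- tabulate(lab)
  keep <- which(sizes >= max(1, min_size))
  map <- integer(length(sizes))
  map[keep] <- seq_along(keep)
  out <- array(0L, dim(lab))
  nz <- lab > 0L
  out[nz] <- map[lab[nz]]
  out
}

new_segmentation <- function(labels, threshold = NA, method = list()) {
  n <- max(labels)
  sizes <- if (n > 0) tabulate(labels, nbins = n) else integer(0)
  cent <- NULL
  if (n > 0) {
    idx <- which(labels > 0)
    ai <- arrayInd(idx, dim(labels))
    l <- labels[idx]
    cent <- cbind(
      x = tapply(ai[, 1], l, mean),
      y = tapply(ai[, 2], l, mean),
      z = tapply(ai[, 3], l, mean))
  }
  structure(list(labels = labels, n_components = n, sizes = sizes,
                 centroids = cent, threshold = threshold, method = method),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d component(s)%s\n", x$n_components,
              if (!is.na(x$threshold))
                sprintf(", threshold %.4g", x$threshold) else ""))
  invisible(x)
}

#' 3D seeded watershed segmentation
#'
#' Smooths the volume (Gaussian, `sigma` voxels - stabilizes seeds on noisy
#' reconstructions), finds seeds as the h-maxima (regional maxima persisting
#' after suppressing peaks of prominence below `h`, via grayscale
#' reconstruction by dilation), and floods the inverted intensity from the
#' seeds with a priority queue, restricted to `mask`. Increasing `h` can
#' only merge seeds, so the label count is non-increasing in `h`.
#'
#' @param volume 3D numeric array (bright objects).
#' @param h seed prominence, in the volume's intensity units (> 0).
#' @param mask optional logical array restricting the flooding (default:
#'   everywhere).
#' @param sigma Gaussian pre-smoothing in voxels (0 disables).
#' @return a `segmentation` object (empty, with a warning, if no seeds).
#' @export
seeded_watershed_3d <- function(volume, h, mask = NULL, sigma = 1) {
  stopifnot(h > 0)
  volume <- as_density_array(volume)
  if (is.null(mask)) mask <- array(TRUE, dim(volume))
  sm <- gaussian_smooth3d(volume, sigma)
  no_seeds <- !any(mask) || diff(range(sm[mask])) <= h
  if (!no_seeds) {
    hm <- cpp_reconstruct_dilation(sm - h, sm)
    seed_mask <- cpp_regional_maxima(hm) & mask
    dim(seed_mask) <- dim(volume)
    seeds <- cpp_label3d(seed_mask, 26L)
  }
  if (no_seeds || max(seeds) == 0L) {
    warning("no watershed seeds found")
    return(new_segmentation(array(0L, dim(volume)),
                            method = list(type = "watershed", h = h,
                                          sigma = sigma)))
  }
  lab <- cpp_watershed3d(-sm, seeds, mask)
  new_segmentation(lab, method = list(type = "watershed", h = h,
                                      sigma = sigma))
}

#' Dice overlap coefficient of two masks
#' @param a,b logical arrays.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
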