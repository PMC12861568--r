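# Electron densitometry: delta -> electron density, paraffin-anchored
# calibration, and per-ROI density statistics (the quantitative
# virtual-histology readout).

#' Refractive-index decrement to electron density
#'
#' Inverse of [rho_to_delta()]: `rho_e = 2 pi delta / (r_e lambda^2)`.
#' Applied to a background-referenced tomogram this yields electron density
#' *relative* to the embedding paraffin; [calibrate()] then anchors the
#' absolute scale.
#'
#' @param tomogram a [fbp()] tomogram or plain array/number of delta values.
#' @param lambda wavelength, nm.
#' @return electron density (e/nm^3), same shape.
#' @export
delta_to_rho <- function(tomogram, lambda) {
  2 * pi / (.r_e * lambda^2) * unclass(tomogram)
}

#' Electron density of a compound from its mass density
#'
#' `rho_e = rho_m * N_A * Z / M`, converted to e/nm^3. The defaults give the
#' electron density of CH2 paraffin at 0.9554 g/cm^3 - the calibration
#' reference of the embedding medium, 328 e/nm^3 after integer rounding.
#'
#' @param mass_density g/cm^3.
#' @param n_electrons electrons per formula unit (CH2: 6 + 2).
#' @param molar_mass g/mol of the formula unit (CH2: 14.0266).
#' @return electron density in e/nm^3.
#' @export
#' @examples
#' electron_density_formula()          # paraffin reference, ~328
electron_density_formula <- function(mass_density = 0.9554,
                                     n_electrons = 8,
                                     molar_mass = 14.0266) {
  avogadro <- 6.02214076e23
  mass_density * avogadro * n_electrons / molar_mass / 1e21
}

#' Paraffin reference electron density (e/nm^3)
#' @param rounded round to integer (the conventional 328).
#' @export
paraffin_reference <- function(rounded = TRUE) {
  x <- electron_density_formula()
  if (rounded) round(x) else x
}

#' Anchor a relative density volume on the paraffin reference
#'
#' The physical scale of the densitometry map is already fixed by
#' [delta_to_rho()]; phase retrieval only leaves the DC offset
#' unconstrained. Calibration therefore adds the constant offset that makes
#' the median over a known paraffin mask equal the reference value
#' (one-point, offset-only calibration; the median is robust to residual
#' rings).
#'
#' @param volume 3D array of relative electron density, e/nm^3.
#' @param paraffin_mask logical array marking pure-paraffin voxels
#'   (>= 1000 voxels recommended).
#' @param reference paraffin electron density, e/nm^3.
#' @return object of class `calibrated_volume`: the offset volume with a
#'   `calibration` attribute (reference, offset, mask size).
#' @export
calibrate <- function(volume, paraffin_mask, reference = 328) {
  volume <- unclass(as_density_array(volume))
  if (!any(paraffin_mask)) stop("empty paraffin mask")
  n <- sum(paraffin_mask)
  if (n < 1000)
    warning("paraffin mask has fewer than 1000 voxels; the anchor may be noisy")
  offset <- reference - stats::median(volume[paraffin_mask])
  out <- volume + offset
  attr(out, "calibration") <- list(reference = reference, offset = offset,
                                   n_mask = n)
  class(out) <- c("calibrated_volume", class(out))
  out
}

#' @export
print.calibrated_volume <- function(x, ...) {
  cal <- attr(x, "calibration")
  cat(sprintf(
    "calibrated_volume: %s voxels; paraffin anchor %g e/nm^3 (offset %+.3g over %d mask voxels)\n",
    paste(dim(x), collapse = " x "), cal$reference, cal$offset, cal$n_mask))
  invisible(x)
}

#' Per-ROI electron-density statistics
#'
#' Distribution summaries of the calibrated density over (optionally
#' eroded) label masks: n, mean, median, sd, quartiles and Tukey whiskers
#' (most extreme data within 1.5 IQR of the quartiles), in absolute e/nm^3,
#' plus the relative values (minus the paraffin reference). One erosion
#' step is applied by default to exclude partial-volume shells at
#' compartment boundaries.
#'
#' @param volume a [calibrate()]d volume (or plain array of e/nm^3).
#' @param labels label volume aligned with `volume` (see [make_phantom()]).
#' @param ids label ids to summarize (default: all labels > 0).
#' @param erosion number of 6-connected erosion steps applied to each mask.
#' @param reference paraffin reference used for the relative columns
#'   (defaults to the volume's calibration record, else 328).
#' @return data frame of class `roi_stats`, one row per label (labels empty
#'   after erosion are skipped with a warning); carries class/compartment
#'   columns when `labels` has a legend.
#' @export
roi_stats <- function(volume, labels, ids = NULL, erosion = 1L,
                      reference = NULL) {
  if (!identical(dim(volume), dim(labels)))
    stop("volume and label grids have different shapes")
  reference <- reference %||%
    attr(volume, "calibration")$reference %||% 328
  legend <- attr(labels, "legend")
  if (is.null(ids)) {
    ids <- sort(unique(as.integer(labels)))
    ids <- ids[ids > 0]
  }
  rows <- lapply(ids, function(id) {
    mask <- array(labels == id, dim(labels))
    if (erosion > 0) mask <- erode_mask(mask, erosion)
    if (!any(mask)) {
      warning(sprintf("label %d empty after erosion: skipped", id))
      return(NULL)
    }
    x <- as.numeric(volume[mask])
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    data.frame(label = id, n_voxels = length(x),
               mean = mean(x), median = q[2],
               sd = if (length(x) > 1) stats::sd(x) else 0,
               q1 = q[1], q3 = q[3],
               whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3] + 1.5 * iqr]),
               rel_mean = mean(x) - reference,
               rel_median = q[2] - reference)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no labels left to summarize")
  if (!is.null(legend) && nrow(legend)) {
    m <- match(out$label, legend$label)
    out$class <- legend$class[m]
    out$compartment <- legend$compartment[m]
    out$structure <- legend$structure[m]
  }
  attr(out, "reference") <- reference
  class(out) <- c("roi_stats", class(out))
  out
}
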