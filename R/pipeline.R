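# End-to-end orchestration: phantom -> acquire -> retrieve -> reconstruct ->
# calibrate -> quantify -> report, with per-stage artifacts, checksums and
# a run manifest. All randomness derives from the master seed, so a re-run
# with the same configuration reproduces every deterministic artifact.

#' Retrieve phase maps for every projection of a hologram stack
#'
#' Applies the configured retrieval scheme angle by angle: multi-distance
#' CTF, single-(shortest-)distance Paganin, or CTF followed by NLT
#' refinement.
#'
#' @param stack a `hologram_stack` from [acquire()].
#' @param config a [retrieval_config()].
#' @return array `nu x nv x n_angles` of phase maps (radians, relative to
#'   the paraffin border), with the configuration attached as attribute
#'   `provenance`.
#' @export
retrieve_phase <- function(stack, config = retrieval_config()) {
  I <- stack$intensities
  d <- dim(I)
  optics <- stack$optics
  phase <- array(0, d[1:3])
  jmin <- which.min(optics$distances)
  # known-paraffin band: the outer half of the acquisition margin, far from
  # both the specimen and its strongest fringes; a degree-1 fit anchors the
  # per-projection offset and tilt without extrapolation risk
  m <- optics$fov_margin %||% 0L
  band <- NULL
  if (m >= 16) {
    w <- m %/% 2L
    band <- matrix(FALSE, d[1], d[2])
    band[c(seq_len(w), d[1] - seq_len(w) + 1L), ] <- TRUE
    band[, c(seq_len(w), d[2] - seq_len(w) + 1L)] <- TRUE
  }
  for (a in seq_len(d[3])) {
    holos <- lapply(seq_len(d[4]), function(j) I[, , a, j])
    phi_a <- switch(config$method,
      ctf = ctf_retrieve(holos, optics$distances, optics$lambda,
                         optics$px_eff, config),
      paganin = paganin_retrieve(holos[[jmin]], optics$lambda,
                                 optics$distances[jmin], optics$px_eff,
                                 config$kappa),
      nlt = {
        init <- ctf_retrieve(holos, optics$distances, optics$lambda,
                             optics$px_eff, config)
        nlt_refine(init, holos, optics$distances, optics$lambda,
                   optics$px_eff, config)$phi
      })
    if (!is.null(band)) phi_a <- flatten_phase(phi_a, band, degree = 1L)
    phase[, , a] <- phi_a
  }
  attr(phase, "provenance") <- config
  attr(phase, "angles") <- stack$angles
  phase
}

#' Reconstruct a tomogram from a phase-map stack
#'
#' Rotation-axis correction (cross-correlation of opposing projections),
#' ring suppression, 360-to-180-degree folding and filtered back
#' projection, returning the volume of the refractive-index decrement
#' relative to the embedding.
#'
#' @param phase array `nu x nv x n_angles` from [retrieve_phase()].
#' @param angles projection angles, degrees (default: attribute of
#'   `phase`).
#' @param optics the [optics_config()] used for the acquisition.
#' @param fold fold the 360-degree scan onto 180 degrees.
#' @param ring_window running-median width for [remove_rings()]; 0
#'   disables.
#' @param filter FBP filter name.
#' @return a `tomogram` (see [fbp()]).
#' @export
reconstruct_tomogram <- function(phase, optics, angles = NULL, fold = TRUE,
                                 ring_window = 11L,
                                 filter = "ram-lak") {
  angles <- angles %||% attr(phase, "angles")
  if (is.null(angles)) stop("projection angles required")
  m <- optics$fov_margin %||% 0L
  if (m > 0) {
    nv <- dim(phase)[2] - 2L * m
    phase <- phase[, m + seq_len(nv), , drop = FALSE]
  }
  sino <- phase_to_sinograms(phase)
  if (ring_window > 0) sino <- remove_rings(sino, ring_window)
  # axis correction from the half-turn-averaged, ring-corrected projections:
  # averaging over angles suppresses per-projection noise, and the ring
  # correction has already removed the angle-invariant fixed pattern that
  # would otherwise correlate with its own mirror image
  lo <- (angles %% 360) < 180
  p0 <- apply(sino[, lo, , drop = FALSE], c(1, 3), mean)
  p180 <- apply(sino[, !lo, , drop = FALSE], c(1, 3), mean)
  axis_offset <- tryCatch(
    find_rotation_axis(p0, p180),
    warning = function(w) { warning(conditionMessage(w)); 0 })
  if (fold) {
    folded <- suppressWarnings(fold_360(sino, angles, axis_offset))
    sino <- folded$sinogram
    angles <- folded$angles
    axis_offset <- 0  # folding already applied the correction
  }
  fbp(sino, angles, filter = filter, voxel_size = optics$px_eff,
      lambda = optics$lambda, axis_offset = axis_offset,
      nx = dim(sino)[1] - 2L * m)
}

#' Calibrate a tomogram and quantify per-compartment densities
#'
#' Converts delta to relative electron density, anchors the offset on the
#' paraffin background (median over an eroded background mask restricted to
#' the well-sampled inscribed cylinder), and summarizes every labelled
#' compartment with [roi_stats()].
#'
#' @param tomogram from [reconstruct_tomogram()].
#' @param labels ground-truth label volume (for mask definitions).
#' @param optics the acquisition [optics_config()].
#' @param reference paraffin reference density, e/nm^3.
#' @param erosion erosion steps for the ROI masks.
#' @param mask_erosion erosion steps for the paraffin calibration mask.
#' @return list with `calibrated` (volume), `stats` ([roi_stats()] table),
#'   `calibration` (record).
#' @export
quantify_density <- function(tomogram, labels, optics, reference = 328,
                             erosion = 1L, mask_erosion = 2L) {
  rho_rel <- delta_to_rho(tomogram, optics$lambda)
  d <- dim(rho_rel)
  paraffin <- array(labels == 0L, d)
  if (mask_erosion > 0) paraffin <- erode_mask(paraffin, mask_erosion)
  # keep the anchor inside the tomographically well-sampled cylinder
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  r2 <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2, "+")
  paraffin <- paraffin & array(rep(r2 <= (0.45 * d[1])^2, d[3]), d)
  calibrated <- calibrate(rho_rel + reference, paraffin, reference)
  st <- roi_stats(calibrated, labels, erosion = erosion,
                  reference = reference)
  list(calibrated = calibrated, stats = st,
       calibration = attr(calibrated, "calibration"))
}

#' Full run configuration
#'
#' @param phantom a [phantom_config()].
#' @param optics an [optics_config()].
#' @param retrieval a [retrieval_config()].
#' @param recon list: `fold`, `ring_window`, `filter`.
#' @param calib list: `reference`, `erosion`, `mask_erosion`.
#' @param seed master seed (propagated to phantom and acquisition).
#' @param outdir artifact directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       optics = optics_config(),
                       retrieval = retrieval_config(),
                       recon = list(fold = TRUE, ring_window = 11L,
                                    filter = "ram-lak"),
                       calib = list(reference = 328, erosion = 1L,
                                    mask_erosion = 2L),
                       seed = 1L, outdir = tempfile("xpct_run_")) {
  phantom$seed <- as.integer(seed)
  structure(list(phantom = phantom, optics = optics,
                 retrieval = retrieval, recon = recon, calib = calib,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Default study configuration
#'
#' A 160^3 phantom at 100 nm voxels holding one large neuron soma with
#' nucleus/nucleolus, a Lewy body with rim inclusions, 18 GvD vacuoles with
#' paraffin-density lumens, a neuromelanin cluster and a Hirano body
#' protruding through the soma border, plus three extrasomal cored plaques and
#' a vessel segment; acquired at 17.1 keV over 181 angles and 4 distances
#' with Poisson noise, retrieved by multi-distance CTF.
#'
#' @param seed master seed.
#' @param outdir artifact directory.
#' @param noiseless disable photon noise and detector gain (for oracle
#'   tests).
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("xpct_run_"),
                               noiseless = FALSE) {
  structures <- list(
    neuron(center = c(80, 80, 88), soma_radius = 5800,
           nucleus_center = c(80, 102, 94), nucleus_radius = 1400,
           nucleolus_radius = 450),
    lewy_body(center = c(64, 68, 70), core_radius = 1500,
              halo_radius = 2500, rim_n = 6, rim_diameter = 900),
    nmg_cluster(center = c(58, 102, 112), region_radius = 1100),
    hirano_body(center = c(102, 94, 42), length = 4000, radius = 600,
                orientation = c(0.1, 0.05, -0.99)),
    gvd(center = c(101, 71, 108), n_vacuoles = 18, vacuole_radius = 600,
        grain_radius = 250, region_radius = 2500),
    plaque(center = c(86, 86, 20), core_radius = 600,
           shell_radius = 1000),
    plaque(center = c(124, 80, 142), core_radius = 600,
           shell_radius = 1000),
    plaque(center = c(100, 52, 24), core_radius = 600,
           shell_radius = 1000),
    vessel(center = c(120, 80, 26), radius = 700, wall_thickness = 300,
           length = 7000, axis = c(0, 1, 0))
  )
  optics <- optics_config(
    photons_per_pixel = if (noiseless) Inf else 5000,
    flat_field_amp = if (noiseless) 0 else 0.05)
  run_config(
    phantom = phantom_config(shape = c(160, 160, 160), voxel_size = 100,
                             background_rho = 328,
                             structures = structures, seed = seed),
    optics = optics, seed = seed, outdir = outdir)
}

pipeline_stage_order <- c("phantom", "acquire", "retrieve", "reconstruct",
                          "calibrate", "quantify", "report")

#' Run the virtual-histology pipeline
#'
#' Executes the requested stages in their fixed order, writing each stage's
#' artifacts (TIFF volumes/stacks with JSON sidecars, CSV tables, a report
#' plot) under `config$outdir` and recording them in a run manifest with
#' md5 checksums and timings. Stages not requested are loaded from their
#' artifacts (verified against the manifest; tampering raises a checksum
#' error), so a run can be resumed stage by stage.
#'
#' @param config a [run_config()].
#' @param stages subset of `phantom`, `acquire`, `retrieve`, `reconstruct`,
#'   `calibrate`, `quantify`, `report` (default: all).
#' @return object of class `run_manifest` (invisibly contains the in-memory
#'   state as attribute `state`).
#' @export
run_pipeline <- function(config, stages = pipeline_stage_order) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stage_order, several.ok = TRUE)
  stages <- intersect(pipeline_stage_order, stages)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_manifest(out)
  manifest$config_hash <- config_hash(config)
  st <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    files <- fun()
    manifest$stages[[name]] <<- list(
      files = as.list(setNames(vapply(file.path(out, files), file_md5,
                                      character(1)), files)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    write_manifest(manifest, out)
  }

  need <- function(field, stage, loader) {
    if (!is.null(st[[field]])) return(st[[field]])
    v <- tryCatch(loader(), error = function(e)
      stop(sprintf("missing input for this stage: run stage '%s' first (%s)",
                   stage, conditionMessage(e)), call. = FALSE))
    st[[field]] <- v
    v
  }

  verify <- function(file) {
    rec <- NULL
    for (s in manifest$stages) if (!is.null(s$files[[file]]))
      rec <- s$files[[file]]
    path <- file.path(out, file)
    if (!is.null(rec) && file.exists(path) && !identical(file_md5(path), rec))
      stop("checksum mismatch for artifact: ", file)
    invisible(TRUE)
  }

  run_stage("phantom", function() {
    st$phantom <- make_phantom(config$phantom)
    write_volume(st$phantom$density, file.path(out, "phantom_density"),
                 meta = list(seed = config$seed,
                             background_rho = config$phantom$background_rho))
    lab <- st$phantom$labels
    write_volume(array(as.numeric(lab), dim(lab)),
                 file.path(out, "phantom_labels"),
                 voxel_size = config$phantom$voxel_size,
                 meta = list(legend = attr(lab, "legend")))
    write_table_csv(st$phantom$truth, file.path(out, "truth.csv"))
    c("phantom_density.tif", "phantom_density.json",
      "phantom_labels.tif", "phantom_labels.json", "truth.csv")
  })

  load_phantom <- function() {
    verify("phantom_density.tif"); verify("phantom_labels.tif")
    dens <- read_volume(file.path(out, "phantom_density"))
    labm <- read_volume(file.path(out, "phantom_labels"))
    lab <- array(as.integer(round(labm)), dim(labm))
    legend <- as.data.frame(attr(labm, "meta")$legend)
    attr(lab, "legend") <- legend
    class(lab) <- c("label_volume", class(lab))
    dens <- ed_volume(array(as.numeric(dens), dim(dens)),
                      attr(dens, "voxel_size"),
                      attr(dens, "meta")$background_rho)
    list(density = dens, labels = lab,
         truth = read_table_csv(file.path(out, "truth.csv")))
  }

  run_stage("acquire", function() {
    ph <- need("phantom", "phantom", load_phantom)
    st$holograms <- acquire(ph$density, config$optics, seed = config$seed)
    write_stack(st$holograms, file.path(out, "holograms"))
    nd <- dim(st$holograms$intensities)[4]
    c(if (nd > 1) sprintf("holograms_d%d.tif", seq_len(nd)) else
        "holograms.tif",
      "holograms.json")
  })

  load_holograms <- function() {
    arr <- read_stack(file.path(out, "holograms"))
    meta <- attr(arr, "meta")
    list(intensities = arr, angles = meta$angles, optics = config$optics,
         seed = meta$seed)
  }

  run_stage("retrieve", function() {
    ho <- need("holograms", "acquire", load_holograms)
    class(ho) <- "hologram_stack"
    st$phase <- retrieve_phase(ho, config$retrieval)
    write_stack(st$phase, file.path(out, "phase"),
                meta = list(angles = attr(st$phase, "angles"),
                            method = config$retrieval$method))
    c("phase.tif", "phase.json")
  })

  load_phase <- function() {
    verify("phase.tif")
    arr <- read_stack(file.path(out, "phase"))
    ph <- array(arr, dim(arr)[1:3])
    attr(ph, "angles") <- attr(arr, "meta")$angles
    ph
  }

  run_stage("reconstruct", function() {
    phs <- need("phase", "retrieve", load_phase)
    st$tomogram <- reconstruct_tomogram(
      phs, config$optics, fold = config$recon$fold %||% TRUE,
      ring_window = config$recon$ring_window %||% 11L,
      filter = config$recon$filter %||% "ram-lak")
    write_volume(unclass(st$tomogram), file.path(out, "tomogram"),
                 voxel_size = config$optics$px_eff,
                 meta = list(filter = attr(st$tomogram, "filter"),
                             n_angles = attr(st$tomogram, "n_angles"),
                             axis_offset = attr(st$tomogram, "axis_offset")))
    c("tomogram.tif", "tomogram.json")
  })

  load_tomogram <- function() {
    verify("tomogram.tif")
    v <- read_volume(file.path(out, "tomogram"))
    array(v, dim(v))
  }

  do_quantify <- function() {
    ph <- need("phantom", "phantom", load_phantom)
    tg <- need("tomogram", "reconstruct", load_tomogram)
    st$quant <- quantify_density(
      tg, ph$labels, config$optics,
      reference = config$calib$reference %||% 328,
      erosion = config$calib$erosion %||% 1L,
      mask_erosion = config$calib$mask_erosion %||% 2L)
    st$quant
  }

  run_stage("calibrate", function() {
    q <- do_quantify()
    write_volume(unclass(q$calibrated), file.path(out, "calibrated"),
                 voxel_size = config$optics$px_eff)
    jsonlite::write_json(q$calibration, file.path(out, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    c("calibrated.tif", "calibrated.json", "calibration.json")
  })

  run_stage("quantify", function() {
    if (is.null(st$quant)) do_quantify()
    write_table_csv(st$quant$stats, file.path(out, "roi_stats.csv"))
    "roi_stats.csv"
  })

  run_stage("report", function() {
    if (is.null(st$quant)) do_quantify()
    write_table_csv(st$quant$stats, file.path(out, "roi_stats.csv"))
    ph <- need("phantom", "phantom", load_phantom)
    groups <- class_density_samples(st$quant$calibrated, ph$labels)
    rep <- density_report(groups)
    write_table_csv(rep$report, file.path(out, "report.csv"))
    grDevices::png(file.path(out, "report.png"), width = 900, height = 600)
    print(rep$plot)
    grDevices::dev.off()
    c("report.csv", "report.png")
  })

  write_manifest(manifest, out)
  res <- manifest_object(manifest)
  attr(res, "state") <- st
  invisible(res)
}

#' Per-class relative density samples from a calibrated volume
#'
#' Collects eroded per-compartment voxel densities (relative to the
#' reference) grouped by `class:compartment` for multi-compartment classes
#' and by class otherwise; used for the report's box plots and pairwise
#' tests.
#'
#' @param calibrated a [calibrate()]d volume.
#' @param labels label volume with legend.
#' @param erosion erosion steps per mask.
#' @return named list of numeric vectors.
#' @export
class_density_samples <- function(calibrated, labels, erosion = 1L) {
  stats_df <- roi_stats(calibrated, labels, erosion = erosion)
  reference <- attr(stats_df, "reference")
  legend <- attr(labels, "legend")
  out <- list()
  for (i in seq_len(nrow(stats_df))) {
    id <- stats_df$label[i]
    nm <- if (!is.null(legend) && id %in% legend$label) {
      cls <- legend$class[legend$label == id]
      cmp <- legend$compartment[legend$label == id]
      if (sum(legend$class == cls) > 1) paste(cls, cmp, sep = ":") else cls
    } else as.character(id)
    mask <- array(labels == id, dim(labels))
    if (erosion > 0) mask <- erode_mask(mask, erosion)
    out[[nm]] <- as.numeric(calibrated[mask]) - reference
  }
  out
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL   # the hash identifies the computation, not its location
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(
    rapply(cfg, unclass, how = "replace"),
    auto_unbox = TRUE, digits = NA, force = TRUE)), tf)
  file_md5(tf)
}

read_manifest <- function(outdir) {
  p <- file.path(outdir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else
    list(config_hash = NULL, stages = list())
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

manifest_object <- function(manifest) {
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (config", substr(x$config_hash, 1, 8), ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-11s %5.1fs  %d file(s)\n", nm,
                as.numeric(x$stages[[nm]]$elapsed_s),
                length(x$stages[[nm]]$files)))
  invisible(x)
}
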