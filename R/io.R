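#' Write / read a TSL series as NIfTI-1 plus JSON sidecar
#'
#' The 4-D magnitude stack is written as one NIfTI-1 volume with pixel
#' spacing and slice thickness in the header; NIfTI has no native spin-lock
#' field, so the TSL schedule and spin-lock amplitude go to a JSON sidecar
#' next to the volume (`<path>.json`).
#'
#' @param series A `tsl_series`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `write_tsl_series()` invisibly returns the paths written;
#'   `read_tsl_series()` returns a `tsl_series`.
#' @export
write_tsl_series <- function(series, path) {
  stopifnot(inherits(series, "tsl_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$pixel_spacing, series$pixel_spacing,
                           series$slice_thickness, 1)
  RNifti::writeNifti(img, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(tsl_ms = series$tsl_ms,
                            spin_lock_amplitude_hz =
                              series$spin_lock_amplitude_hz,
                            pixel_spacing = series$pixel_spacing,
                            slice_thickness = series$slice_thickness),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' @rdname write_tsl_series
#' @export
read_tsl_series <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing TSL sidecar: ", sidecar, " (field tsl_ms is required)")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$tsl_ms)) stop("sidecar lacks required field 'tsl_ms'")
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  tsl_series(data, meta$tsl_ms,
             spin_lock_amplitude_hz = meta$spin_lock_amplitude_hz %||% NA_real_,
             pixel_spacing = meta$pixel_spacing %||% NA_real_,
             slice_thickness = meta$slice_thickness %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read per-slice contours as JSON
#'
#' Polygons are stored closed, counterclockwise, in 0-based pixel-centre
#' coordinates, one record per slice.
#'
#' @param contours Per-slice contour list (as in a `ground_truth`).
#' @param path JSON path.
#' @param pixel_spacing Spacing metadata stored alongside, mm.
#' @export
write_contours <- function(contours, path, pixel_spacing = NA_real_) {
  recs <- lapply(contours, function(cp) {
    list(slice_index = cp$slice_index,
         epicardial = unname(apply(cp$epicardial, 1, as.numeric,
                                   simplify = FALSE)),
         endocardial = unname(apply(cp$endocardial, 1, as.numeric,
                                    simplify = FALSE)))
  })
  jsonlite::write_json(list(pixel_spacing = pixel_spacing, slices = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj$slices, function(rec) {
    list(slice_index = rec$slice_index,
         epicardial = do.call(rbind, lapply(rec$epicardial, as.numeric)),
         endocardial = do.call(rbind, lapply(rec$endocardial, as.numeric)))
  })
}

#' Write a T1rho map as NIfTI volumes plus a JSON region report
#'
#' @param map A `t1rho_map`.
#' @param prefix Output path prefix; writes `<prefix>_t1rho.nii`,
#'   `<prefix>_s0.nii`, `<prefix>_r2.nii`.
#' @param region_stats Optional list of `region_stats` written to
#'   `<prefix>_regions.json`.
#' @export
write_t1rho_map <- function(map, prefix, region_stats = NULL) {
  stopifnot(inherits(map, "t1rho_map"))
  wr <- function(arr, suffix) {
    img <- RNifti::asNifti(arr)
    if (is.finite(map$pixel_spacing)) {
      RNifti::pixdim(img) <- c(map$pixel_spacing, map$pixel_spacing,
                               map$slice_thickness)
    }
    RNifti::writeNifti(img, paste0(prefix, suffix))
  }
  wr(map$t1rho, "_t1rho.nii")
  wr(map$s0, "_s0.nii")
  wr(map$r_squared, "_r2.nii")
  if (!is.null(region_stats)) {
    jsonlite::write_json(lapply(region_stats, unclass),
                         paste0(prefix, "_regions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(prefix)
}

#' Write phantom ground truth to a directory
#'
#' Labels as integer NIfTI-1, contours and analytic scalars as JSON, the
#' generating configuration as YAML.
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- truth$config
  lab <- RNifti::asNifti(array(as.integer(truth$label_volume),
                               dim = dim(truth$label_volume)))
  RNifti::pixdim(lab) <- c(cfg$pixel_spacing, cfg$pixel_spacing,
                           cfg$slice_thickness)
  RNifti::writeNifti(lab, file.path(dir, "labels.nii"))
  write_contours(truth$contours, file.path(dir, "contours.json"),
                 pixel_spacing = cfg$pixel_spacing)
  jsonlite::write_json(list(
    tissues = PHANTOM_TISSUES,
    true_infarct_perimeter_fraction = truth$true_infarct_perimeter_fraction,
    true_infarct_volume = truth$true_infarct_volume,
    true_lv_myocardial_volume = truth$true_lv_myocardial_volume,
    true_nontransmural_infarct_fraction =
      truth$true_nontransmural_infarct_fraction,
    infarct_slices = truth$infarct_slices
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_phantom_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write / read a phantom configuration as YAML
#' @param config A [phantom_config()].
#' @param path YAML path.
#' @export
write_phantom_config <- function(config, path) {
  lst <- unclass(config)
  lst$tissue_params <- lapply(lst$tissue_params, unclass)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$tissue_params <- lapply(lst$tissue_params, function(p) {
    tissue_params(t1rho = p$t1rho, s0 = p$s0)
  })
  do.call(phantom_config, lst)
}
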