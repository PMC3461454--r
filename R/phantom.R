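#' Tissue relaxation parameters
#'
#' Bundle the spin-lock relaxation time and equilibrium signal amplitude of a
#' tissue compartment.
#'
#' @param t1rho Rotating-frame relaxation time in ms; must be positive.
#' @param s0 Equilibrium signal amplitude in arbitrary units; must be
#'   non-negative.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(t1rho, s0) {
  if (!is.numeric(t1rho) || length(t1rho) != 1L || !is.finite(t1rho) ||
      t1rho <= 0) {
    stop("`t1rho` must be a single positive number (ms)")
  }
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 < 0) {
    stop("`s0` must be a single non-negative number")
  }
  structure(list(t1rho = t1rho, s0 = s0), class = "tissue_params")
}

#' Default tissue parameter set
#'
#' Remote myocardium and infarct T1rho are the in-vivo chronic-infarct values
#' at 3 T with a 500 Hz spin-lock (47.2 ms and 91.7 ms). Blood and background
#' values are not reported at these conditions; the blood defaults are
#' placeholders chosen so that signal ordering on T1rho-weighted images is
#' blood > infarct > myocardium at every spin-lock duration in the schedule.
#'
#' @return Named list of [tissue_params()] for `background`, `blood`,
#'   `myocardium`, `infarct`.
#' @export
default_tissue_params <- function() {
  list(
    background = tissue_params(t1rho = 1, s0 = 0),
    blood      = tissue_params(t1rho = 150, s0 = 120),
    myocardium = tissue_params(t1rho = 47.2, s0 = 100),
    infarct    = tissue_params(t1rho = 91.7, s0 = 100)
  )
}

# canonical tissue ordering; label codes are indices into this vector
PHANTOM_TISSUES <- c("background", "blood", "myocardium", "infarct")

#' Phantom configuration
#'
#' Full generative description of the synthetic short-axis left-ventricle
#' phantom: an annular myocardium (endocardial to epicardial radius) around a
#' circular blood pool, with a sectoral infarct of configurable angular extent
#' and transmural depth growing outward from the endocardium.
#'
#' Geometry defaults follow a high-resolution 3 T cardiac protocol:
#' 192 x 192 matrix at 0.64 mm in-plane, 20 slices of 2.6 mm. The default
#' infarct arc is 21.1% of the endocardial circumference, fully transmural.
#'
#' @param matrix Integer pair `(nx, ny)` of in-plane pixels.
#' @param n_slices Number of short-axis slices.
#' @param pixel_spacing In-plane pixel size, mm (isotropic).
#' @param slice_thickness Slice thickness, mm.
#' @param epi_radius,endo_radius Epicardial/endocardial radii, mm.
#' @param blood_radius Blood-pool radius, mm; must equal `endo_radius`.
#' @param infarct_center_angle Centre of the infarct arc, degrees
#'   counterclockwise from the +x axis.
#' @param infarct_angular_extent Angular extent of the infarct arc, degrees in
#'   `[0, 360]`.
#' @param infarct_transmural_profile Numeric vector of per-angular-bin wall
#'   depth fractions in `[0, 1]` (1 = transmural), spanning the infarct arc in
#'   equal bins counterclockwise.
#' @param apical_extent Integer pair: first and last slice index occupied by
#'   the infarct.
#' @param tissue_params Named list of [tissue_params()]; see
#'   [default_tissue_params()].
#' @param noise_sigma Magnitude-noise level in signal units (default gives
#'   SNR 50 at the default `s0` of 100).
#' @param supersample_factor Integer >= 1; in-plane rasterization supersampling
#'   used to compute partial-volume fractions.
#' @param seed Integer seed used for noise realizations downstream.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(matrix = c(192L, 192L),
                           n_slices = 20L,
                           pixel_spacing = 0.64,
                           slice_thickness = 2.6,
                           epi_radius = 30,
                           endo_radius = 20,
                           blood_radius = endo_radius,
                           infarct_center_angle = 90,
                           infarct_angular_extent = 0.211 * 360,
                           infarct_transmural_profile = 1,
                           apical_extent = c(1L, n_slices),
                           tissue_params = default_tissue_params(),
                           noise_sigma = 2,
                           supersample_factor = 4L,
                           seed = 1L) {
  cfg <- list(
    matrix = as.integer(matrix),
    n_slices = as.integer(n_slices),
    pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness,
    epi_radius = epi_radius,
    endo_radius = endo_radius,
    blood_radius = blood_radius,
    infarct_center_angle = infarct_center_angle %% 360,
    infarct_angular_extent = infarct_angular_extent,
    infarct_transmural_profile = as.numeric(infarct_transmural_profile),
    apical_extent = as.integer(apical_extent),
    tissue_params = tissue_params,
    noise_sigma = noise_sigma,
    supersample_factor = as.integer(supersample_factor),
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$matrix) == 2L, all(cfg$matrix >= 8L),
            cfg$n_slices >= 1L, cfg$pixel_spacing > 0,
            cfg$slice_thickness > 0, cfg$supersample_factor >= 1L)
  if (cfg$endo_radius >= cfg$epi_radius) {
    stop("configuration error: endo_radius (", cfg$endo_radius,
         " mm) must be smaller than epi_radius (", cfg$epi_radius, " mm)")
  }
  if (cfg$blood_radius != cfg$endo_radius) {
    stop("configuration error: blood_radius must equal endo_radius")
  }
  half_fov <- min(cfg$matrix) / 2 * cfg$pixel_spacing
  if (cfg$epi_radius >= half_fov) {
    stop("configuration error: epi_radius (", cfg$epi_radius,
         " mm) does not fit inside the matrix (half-FOV ", half_fov, " mm)")
  }
  if (cfg$infarct_angular_extent < 0 || cfg$infarct_angular_extent > 360) {
    stop("infarct_angular_extent must lie in [0, 360] degrees")
  }
  prof <- cfg$infarct_transmural_profile
  if (length(prof) < 1L || any(!is.finite(prof)) ||
      any(prof < 0) || any(prof > 1)) {
    stop("infarct_transmural_profile entries must lie in [0, 1]")
  }
  if (length(cfg$apical_extent) != 2L ||
      cfg$apical_extent[1] < 1L || cfg$apical_extent[2] > cfg$n_slices ||
      cfg$apical_extent[1] > cfg$apical_extent[2]) {
    stop("apical_extent must be an increasing slice-index pair within 1..n_slices")
  }
  missing_t <- setdiff(PHANTOM_TISSUES, names(cfg$tissue_params))
  if (length(missing_t)) {
    stop("tissue_params missing: ", paste(missing_t, collapse = ", "))
  }
  invisible(cfg)
}

# block-average a (nx*f) x (ny*f) matrix down to nx x ny
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  nx <- nrow(m) / f
  ny <- ncol(m) / f
  dim(m) <- c(f, nx, f * ny)
  m <- colMeans(m)               # nx x (f*ny)
  dim(m) <- c(nx, f, ny)
  m <- aperm(m, c(2L, 1L, 3L))   # f x nx x ny
  m <- colMeans(m)
  dim(m) <- c(nx, ny)
  m
}

# rasterize one slice type at supersampled resolution; returns pv [nx,ny,4]
rasterize_slice <- function(cfg, with_infarct) {
  nx <- cfg$matrix[1]; ny <- cfg$matrix[2]; f <- cfg$supersample_factor
  ps <- cfg$pixel_spacing
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  sub <- function(n) (seq_len(n * f) - 0.5) / f - 0.5  # 0-based subpixel centres
  dx <- (sub(nx) - cx) * ps
  dy <- (sub(ny) - cy) * ps
  DX <- matrix(dx, nx * f, ny * f)
  DY <- matrix(dy, nx * f, ny * f, byrow = TRUE)
  r <- sqrt(DX^2 + DY^2)

  lab <- matrix(1L, nx * f, ny * f)             # background
  lab[r < cfg$endo_radius] <- 2L                # blood
  wall <- r >= cfg$endo_radius & r < cfg$epi_radius
  lab[wall] <- 3L                               # myocardium

  ext <- cfg$infarct_angular_extent
  prof <- cfg$infarct_transmural_profile
  if (with_infarct && ext > 0 && any(prof > 0)) {
    theta <- (atan2(DY, DX) * 180 / pi) %% 360
    a0 <- (cfg$infarct_center_angle - ext / 2) %% 360
    d <- (theta - a0) %% 360
    in_arc <- wall & d < ext
    depth <- (r - cfg$endo_radius) / (cfg$epi_radius - cfg$endo_radius)
    nb <- length(prof)
    bin <- pmin(nb, floor(d / ext * nb) + 1L)
    frac <- matrix(prof[bin], nrow(lab), ncol(lab))
    lab[in_arc & depth < frac] <- 4L
  }

  pv <- array(0, dim = c(nx, ny, 4L))
  for (t in 1:4) pv[, , t] <- block_mean(lab == t, f)
  pv
}

#' Generate the synthetic left-ventricle phantom
#'
#' Rasterizes the annulus and infarct sector on a grid supersampled in-plane
#' by `supersample_factor`, block-averages to obtain per-voxel partial-volume
#' fractions, assigns a majority label per voxel, traces epicardial and
#' endocardial contours as ordered closed counterclockwise polygons, and
#' computes all ground-truth quantities analytically from the configuration
#' (not from the raster).
#'
#' @param config A [phantom_config()].
#' @return An object of class `ground_truth` with elements `label_volume`
#'   (integer array, levels in `attr(,"tissues")`), `partial_volume_maps`
#'   (4-D array `[x, y, slice, tissue]`), `contours` (per-slice list with
#'   `epicardial`/`endocardial` polygons in 0-based pixel-centre coordinates),
#'   the analytic `true_*` scalars, and the generating `config`.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  cfg <- config
  nx <- cfg$matrix[1]; ny <- cfg$matrix[2]; nz <- cfg$n_slices

  inf_slices <- seq(cfg$apical_extent[1], cfg$apical_extent[2])
  has_infarct <- cfg$infarct_angular_extent > 0 &&
    any(cfg$infarct_transmural_profile > 0)
  if (!has_infarct) inf_slices <- integer(0)

  pv_inf <- rasterize_slice(cfg, with_infarct = TRUE)
  pv_rem <- if (has_infarct && length(inf_slices) < nz) {
    rasterize_slice(cfg, with_infarct = FALSE)
  } else if (!has_infarct) pv_inf else NULL

  pv <- array(0, dim = c(nx, ny, nz, 4L))
  for (z in seq_len(nz)) {
    pv[, , z, ] <- if (z %in% inf_slices || !has_infarct) pv_inf else pv_rem
  }

  # majority label; ties resolved toward the later (rarer) tissue
  flat <- matrix(pv, ncol = 4L)
  lab <- max.col(flat, ties.method = "last")
  label_volume <- array(as.integer(lab), dim = c(nx, ny, nz))
  attr(label_volume, "tissues") <- PHANTOM_TISSUES

  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  ps <- cfg$pixel_spacing
  epi_poly <- circle_polygon(c(cx, cy), cfg$epi_radius / ps)
  endo_poly <- circle_polygon(c(cx, cy), cfg$endo_radius / ps)
  contours <- lapply(seq_len(nz), function(z) {
    list(slice_index = z, epicardial = epi_poly, endocardial = endo_poly)
  })

  # analytic ground truth
  w <- cfg$epi_radius - cfg$endo_radius
  th <- cfg$slice_thickness
  lv_vol <- pi * (cfg$epi_radius^2 - cfg$endo_radius^2) * th * nz / 1000
  prof <- cfg$infarct_transmural_profile
  nb <- length(prof)
  if (has_infarct) {
    dth <- cfg$infarct_angular_extent / nb * pi / 180   # bin angle, rad
    r_out <- cfg$endo_radius + prof * w
    bin_vol <- dth / 2 * (r_out^2 - cfg$endo_radius^2) *
      th * length(inf_slices) / 1000                    # mL per bin
    inf_vol <- sum(bin_vol)
    perim_frac <- (cfg$infarct_angular_extent / 360) * mean(prof > 0) *
      (length(inf_slices) / nz)
    nontrans_frac <- if (inf_vol > 0) sum(bin_vol[prof < 1]) / inf_vol else 0
  } else {
    inf_vol <- 0; perim_frac <- 0; nontrans_frac <- 0
  }

  structure(list(
    label_volume = label_volume,
    partial_volume_maps = pv,
    contours = contours,
    true_infarct_perimeter_fraction = perim_frac,
    true_infarct_volume = inf_vol,
    true_lv_myocardial_volume = lv_vol,
    true_nontransmural_infarct_fraction = nontrans_frac,
    infarct_slices = inf_slices,
    config = cfg
  ), class = "ground_truth")
}

#' Voxel volume of a phantom configuration
#' @param config A [phantom_config()].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(config) {
  config$pixel_spacing^2 * config$slice_thickness
}

#' Tissue masks from ground-truth partial volumes
#'
#' `pure_tissue_mask()` selects voxels whose fraction of the named tissue is
#' at least `min_fraction`; `wall_mask()` does the same for the combined
#' myocardium + infarct wall, and is the default analysis mask (with
#' `min_fraction = 1` it excludes every boundary voxel contaminated by blood
#' or background, mimicking a conservatively drawn myocardial contour).
#'
#' @param truth A `ground_truth` object.
#' @param tissue One of `"background"`, `"blood"`, `"myocardium"`, `"infarct"`.
#' @param min_fraction Minimum tissue fraction in `[0, 1]`.
#' @return Logical array `[x, y, slice]`.
#' @export
pure_tissue_mask <- function(truth, tissue, min_fraction = 1) {
  t <- match(match.arg(tissue, PHANTOM_TISSUES), PHANTOM_TISSUES)
  truth$partial_volume_maps[, , , t, drop = FALSE][, , , 1] >=
    min_fraction - 1e-9
}

#' @rdname pure_tissue_mask
#' @export
wall_mask <- function(truth, min_fraction = 1) {
  pv <- truth$partial_volume_maps
  (pv[, , , 3] + pv[, , , 4]) >= min_fraction - 1e-9
}

#' Remote-myocardium reference mask
#'
#' Pure myocardial voxels whose polar angle lies outside the infarct arc
#' widened by `margin_deg` on each side — the automated analogue of a manually
#' drawn remote ROI in the opposite wall.
#'
#' @param truth A `ground_truth` object.
#' @param margin_deg Angular margin, degrees.
#' @return Logical array `[x, y, slice]`.
#' @export
remote_reference_mask <- function(truth, margin_deg = 20) {
  cfg <- truth$config
  m <- pure_tissue_mask(truth, "myocardium")
  ext <- cfg$infarct_angular_extent
  if (ext <= 0 || length(truth$infarct_slices) == 0L) return(m)
  nx <- cfg$matrix[1]; ny <- cfg$matrix[2]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  dx <- matrix(seq_len(nx) - 1 - cx, nx, ny)
  dy <- matrix(seq_len(ny) - 1 - cy, nx, ny, byrow = TRUE)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  a0 <- (cfg$infarct_center_angle - ext / 2 - margin_deg) %% 360
  span <- min(360, ext + 2 * margin_deg)
  outside <- ((theta - a0) %% 360) >= span
  m & array(outside, dim = dim(m))
}

#' Simulate the noiseless T1rho-weighted stack
#'
#' Signal model: partial-volume-weighted mono-exponential rotating-frame
#' decay, `S(TSL) = sum_t frac_t * s0_t * exp(-TSL / T1rho_t)` over the four
#' tissue compartments. The spin-lock amplitude is carried as metadata only
#' (contrast is simulated at a single amplitude).
#'
#' @param truth A `ground_truth` object.
#' @param config The generating [phantom_config()]; defaults to the one stored
#'   in `truth`.
#' @param tsl_ms Strictly increasing spin-lock durations, ms.
#' @param spin_lock_amplitude_hz Spin-lock amplitude metadata, Hz.
#' @return An object of class `tsl_series`: `data` is a 4-D array
#'   `[x, y, slice, tsl]` of magnitudes plus acquisition metadata.
#' @export
simulate_tsl_series <- function(truth, config = truth$config,
                                tsl_ms = c(6, 18, 30, 42, 48),
                                spin_lock_amplitude_hz = 500) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(tsl_ms) < 1L || any(diff(tsl_ms) <= 0)) {
    stop("tsl_ms must be strictly increasing")
  }
  pv <- truth$partial_volume_maps
  dims <- dim(pv)[1:3]
  nt <- length(tsl_ms)
  data <- array(0, dim = c(dims, nt))
  tp <- config$tissue_params
  for (k in seq_len(nt)) {
    sl <- array(0, dim = dims)
    for (t in seq_along(PHANTOM_TISSUES)) {
      p <- tp[[PHANTOM_TISSUES[t]]]
      if (p$s0 > 0) {
        sl <- sl + pv[, , , t] * (p$s0 * exp(-tsl_ms[k] / p$t1rho))
      }
    }
    data[, , , k] <- sl
  }
  tsl_series(data, tsl_ms, spin_lock_amplitude_hz,
             config$pixel_spacing, config$slice_thickness)
}

#' Construct a TSL series container
#' @param data 4-D non-negative magnitude array `[x, y, slice, tsl]`.
#' @param tsl_ms Strictly increasing spin-lock durations, ms.
#' @param spin_lock_amplitude_hz Spin-lock amplitude, Hz (metadata).
#' @param pixel_spacing In-plane pixel size, mm.
#' @param slice_thickness Slice thickness, mm.
#' @return Object of class `tsl_series`.
#' @export
tsl_series <- function(data, tsl_ms, spin_lock_amplitude_hz = NA_real_,
                       pixel_spacing = NA_real_, slice_thickness = NA_real_) {
  stopifnot(length(dim(data)) == 4L)
  if (dim(data)[4] != length(tsl_ms)) {
    stop("4th dimension of data must match length(tsl_ms)")
  }
  if (any(diff(tsl_ms) <= 0)) stop("tsl_ms must be strictly increasing")
  if (min(data) < 0) stop("magnitude data must be non-negative")
  structure(list(data = data, tsl_ms = as.numeric(tsl_ms),
                 spin_lock_amplitude_hz = spin_lock_amplitude_hz,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "tsl_series")
}

# run `expr` under a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Add magnitude noise to a TSL series or image array
#'
#' Rician noise forms the magnitude of `(S + n1, n2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma` (the MRI
#' magnitude-image model); Gaussian noise adds `n1` and clips at zero.
#' Deterministic given `seed`.
#'
#' @param series A `tsl_series`, or a bare numeric array.
#' @param sigma Noise level in signal units; `sigma = 0` returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @param model `"rician"` (default) or `"gaussian"`.
#' @return Same type as the input.
#' @export
add_noise <- function(series, sigma, seed, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single non-negative number")
  }
  if (sigma == 0) return(series)
  is_series <- inherits(series, "tsl_series")
  x <- if (is_series) series$data else series
  noisy <- with_seed(seed, {
    n1 <- array(stats::rnorm(length(x), sd = sigma), dim = dim(x))
    if (model == "rician") {
      n2 <- array(stats::rnorm(length(x), sd = sigma), dim = dim(x))
      sqrt((x + n1)^2 + n2^2)
    } else {
      pmax(x + n1, 0)
    }
  })
  if (is_series) {
    series$data <- noisy
    series
  } else {
    noisy
  }
}

#' Simulate a reference hyperenhancement image
#'
#' A single 3-D image with the intensity ordering of a contrast-enhanced
#' viability scan — infarct hyperintense, remote myocardium suppressed, blood
#' intermediate — on the same phantom geometry, partial-volume weighted, with
#' the same magnitude-noise contract as [add_noise()]. It provides the second
#' modality for method-agreement statistics.
#'
#' @param truth A `ground_truth` object.
#' @param config The generating [phantom_config()].
#' @param means Named per-tissue mean intensities.
#' @param sigma Noise level; defaults to the phantom's `noise_sigma`.
#' @param seed Integer seed; defaults to the phantom's seed.
#' @param model Noise model, see [add_noise()].
#' @return 3-D numeric array `[x, y, slice]`.
#' @export
simulate_reference_modality <- function(truth, config = truth$config,
                                        means = c(background = 0, blood = 60,
                                                  myocardium = 20,
                                                  infarct = 100),
                                        sigma = config$noise_sigma,
                                        seed = config$seed,
                                        model = "rician") {
  stopifnot(inherits(truth, "ground_truth"))
  pv <- truth$partial_volume_maps
  img <- array(0, dim = dim(pv)[1:3])
  for (t in seq_along(PHANTOM_TISSUES)) {
    mu <- means[[PHANTOM_TISSUES[t]]]
    if (mu != 0) img <- img + pv[, , , t] * mu
  }
  add_noise(img, sigma = sigma, seed = seed, model = model)
}
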