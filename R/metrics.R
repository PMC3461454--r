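#' Classify infarct within the myocardium
#'
#' Automated, reproducible surrogate for manual infarct tracing. The default
#' rule on a T1rho map calls a pixel infarct when its value exceeds
#' `mean(remote) + k * sd(remote)` with `k = 5`; alternatives are `"fwhm"`
#' (threshold halfway between the remote mean and the hyperintense maximum)
#' and `"fixed"` (user threshold). The rule and its parameters are recorded
#' in the output for reproducibility.
#'
#' @param x A `t1rho_map` (classification on fitted T1rho) or a numeric array
#'   (classification on signal intensity).
#' @param myocardial_mask Logical array of myocardial pixels.
#' @param remote_mask Logical array: remote reference region, a subset of the
#'   myocardium disjoint from the suspected infarct.
#' @param rule `"mean_sd"`, `"fwhm"`, or `"fixed"`.
#' @param k SD multiplier for `"mean_sd"` (default 5).
#' @param threshold Threshold for `"fixed"`.
#' @return Object of class `infarct_classification` with logical array
#'   `infarct`, the analysis `mask`, and a `method` descriptor.
#' @export
classify_infarct <- function(x, myocardial_mask, remote_mask,
                             rule = c("mean_sd", "fwhm", "fixed"),
                             k = 5, threshold = NULL) {
  rule <- match.arg(rule)
  if (inherits(x, "t1rho_map")) {
    values <- x$t1rho
    usable <- x$valid
  } else {
    values <- x
    usable <- array(TRUE, dim = dim(x))
  }
  stopifnot(all(dim(values) == dim(myocardial_mask)),
            all(dim(values) == dim(remote_mask)))
  rv <- values[remote_mask & usable]
  if (!length(rv)) stop("remote reference region is empty")
  mu <- mean(rv)
  s <- if (length(rv) > 1L) stats::sd(rv) else 0
  thr <- switch(rule,
    mean_sd = {
      if (k == 0) warning("k = 0 thresholds at the remote mean; ",
                          "about half the remote region will exceed it")
      mu + k * s
    },
    fwhm = {
      mv <- values[myocardial_mask & usable]
      (mu + max(mv)) / 2
    },
    fixed = {
      if (is.null(threshold)) stop("rule 'fixed' requires `threshold`")
      threshold
    })
  infarct <- myocardial_mask & usable & !is.na(values) & values > thr
  structure(list(
    infarct = infarct,
    mask = myocardial_mask & usable,
    method = list(rule = rule, k = if (rule == "mean_sd") k else NA_real_,
                  threshold = thr, remote_mean = mu, remote_sd = s,
                  remote_n = length(rv))
  ), class = "infarct_classification")
}

#' Infarct size as an endocardial-perimeter ratio
#'
#' For every slice, each endocardial polyline segment is labelled
#' infarct-adjacent when the majority of classified myocardial pixels of the
#' innermost radial section lying in the segment's angular span (about the
#' cardiac centroid) are infarct; segments whose span contains no pixel take
#' the label of the angularly nearest section-1 pixel. Size is
#' `100 * sum(infarct-adjacent segment lengths) / sum(all segment lengths)`,
#' with lengths summed over all contoured slices before dividing.
#'
#' @param classification An [classify_infarct()] result.
#' @param contours Per-slice contour list (as in a `ground_truth`).
#' @param grid A [build_chord_grid()] result co-registered with the
#'   classification; built from `contours` and the classification mask when
#'   omitted.
#' @return Percentage in `[0, 100]`, with a per-slice breakdown in
#'   `attr(, "per_slice")`.
#' @export
infarct_size_perimeter <- function(classification, contours, grid = NULL) {
  stopifnot(inherits(classification, "infarct_classification"))
  mask <- classification$mask
  nz <- dim(mask)[3]
  miss <- which(vapply(seq_len(nz), function(z) {
    (z > length(contours) || is.null(contours[[z]])) &&
      any(classification$infarct[, , z])
  }, logical(1)))
  if (length(miss)) {
    stop("missing contours for classified slice(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(grid)) grid <- build_chord_grid(contours, mask)
  nx <- dim(mask)[1]

  tot_len <- 0
  inf_len <- 0
  per_slice <- data.frame(slice = integer(), total_mm = numeric(),
                          infarct_mm = numeric())
  for (z in seq_len(min(nz, length(contours)))) {
    cp <- contours[[z]]
    if (is.null(cp)) next
    ctr <- if (!is.na(grid$centroid[z, 1])) grid$centroid[z, ] else
      cardiac_centroid(cp)
    v <- open_polygon(cp$endocardial)
    nseg <- nrow(v)
    vn <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
    seg_len <- sqrt(rowSums((vn - v)^2))
    va <- (atan2(v[, 2] - ctr[2], v[, 1] - ctr[1]) * 180 / pi) %% 360
    key0 <- va[1]
    vkey <- (va - key0) %% 360
    if (any(diff(vkey) <= 0)) {
      stop("endocardial polygon is not star-shaped counterclockwise about ",
           "the centroid on slice ", z)
    }

    sel <- which(grid$radial[, , z] == 1L)
    if (!length(sel)) {
      # no section-1 pixels on this slice: count toward the denominator only
      tot_len <- tot_len + sum(seg_len)
      per_slice <- rbind(per_slice, data.frame(slice = z,
                                               total_mm = sum(seg_len),
                                               infarct_mm = 0))
      next
    }
    px <- (sel - 1L) %% nx
    py <- (sel - 1L) %/% nx
    pth <- (atan2(py - ctr[2], px - ctr[1]) * 180 / pi) %% 360
    pkey <- (pth - key0) %% 360
    lab <- classification$infarct[, , z][sel]

    seg_of_pixel <- findInterval(pkey, vkey)  # in 1..nseg
    frac <- tapply(lab, factor(seg_of_pixel, levels = seq_len(nseg)), mean)
    frac <- as.numeric(frac)
    empty <- is.na(frac)
    if (any(empty)) {
      # nearest pixel by circular angle to the segment midpoint
      mid <- (vkey + c(diff(vkey), 360 - vkey[nseg]) / 2)[empty]
      o <- order(pkey)
      pk <- pkey[o]; lb <- lab[o]
      pos <- findInterval(mid, pk)
      lo <- ifelse(pos == 0L, length(pk), pos)
      hi <- ifelse(pos == length(pk), 1L, pos + 1L)
      dlo <- pmin((mid - pk[lo]) %% 360, (pk[lo] - mid) %% 360)
      dhi <- pmin((mid - pk[hi]) %% 360, (pk[hi] - mid) %% 360)
      frac[empty] <- ifelse(dlo <= dhi, lb[lo], lb[hi])
    }
    inf_seg <- frac > 0.5
    tot_len <- tot_len + sum(seg_len)
    inf_len <- inf_len + sum(seg_len[inf_seg])
    per_slice <- rbind(per_slice,
                       data.frame(slice = z, total_mm = sum(seg_len),
                                  infarct_mm = sum(seg_len[inf_seg])))
  }
  if (tot_len <= 0) stop("no endocardial perimeter available")
  size <- 100 * inf_len / tot_len
  attr(size, "per_slice") <- per_slice
  size
}

#' Chord-based infarct transmurality
#'
#' A (slice, wedge) is infarcted when any of its radial sections is at least
#' half infarct by pixel count, and transmural when all `n_radial` sections
#' are. The transmural percentage is the endocardial arc length of transmural
#' wedges over all infarcted wedges (wedges subtend equal arcs); volume
#' fractions are voxel counts of classified infarct inside non-transmural
#' wedges, relative to total infarct and to the whole myocardial mask.
#'
#' @param classification An [classify_infarct()] result.
#' @param grid A co-registered [build_chord_grid()] result.
#' @return List with `transmural_percent`,
#'   `nontransmural_infarct_volume_fraction` (% of infarct volume),
#'   `nontransmural_lv_fraction` (% of LV myocardial volume), and the
#'   per-(slice, wedge) table `wedges`.
#' @export
transmurality <- function(classification, grid) {
  stopifnot(inherits(classification, "infarct_classification"),
            inherits(grid, "chord_grid"))
  idx <- which(grid$mask & classification$mask)
  if (!length(idx)) stop("empty chord grid / classification overlap")
  nxny <- dim(grid$mask)[1] * dim(grid$mask)[2]
  df <- data.frame(slice = (idx - 1L) %/% nxny + 1L,
                   wedge = grid$wedge[idx],
                   radial = grid$radial[idx],
                   infarct = classification$infarct[idx])
  sec <- stats::aggregate(infarct ~ slice + wedge + radial, data = df,
                          FUN = mean)
  sec$hit <- sec$infarct >= 0.5
  any_hit <- stats::aggregate(hit ~ slice + wedge, data = sec, FUN = any)
  all_hit <- stats::aggregate(hit ~ slice + wedge, data = sec, FUN = all)$hit
  n_sec <- stats::aggregate(hit ~ slice + wedge, data = sec, FUN = length)$hit
  wtab <- data.frame(slice = any_hit$slice, wedge = any_hit$wedge,
                     infarcted = any_hit$hit, n_sections = n_sec)
  wtab$transmural <- wtab$infarcted & all_hit &
    wtab$n_sections == grid$n_radial

  n_inf_wedges <- sum(wtab$infarcted)
  n_trans <- sum(wtab$transmural)
  transmural_percent <- if (n_inf_wedges > 0) {
    100 * n_trans / n_inf_wedges
  } else NA_real_

  key <- paste(df$slice, df$wedge)
  nt_key <- paste(wtab$slice, wtab$wedge)[wtab$infarcted & !wtab$transmural]
  inf_vox <- sum(df$infarct)
  nt_vox <- sum(df$infarct & key %in% nt_key)
  list(
    transmural_percent = transmural_percent,
    nontransmural_infarct_volume_fraction =
      if (inf_vox > 0) 100 * nt_vox / inf_vox else 0,
    nontransmural_lv_fraction = 100 * nt_vox / nrow(df),
    wedges = wtab
  )
}

#' Tissue mass from voxel counts
#'
#' `mass = count * voxel_volume_mm3 * 1e-3 mL/mm^3 * 1.06 g/mL`, the standard
#' myocardial tissue-density assumption.
#'
#' @param voxel_count Non-negative voxel count(s).
#' @param voxel_volume_mm3 Voxel volume, mm^3.
#' @param density_g_per_ml Tissue density, g/mL (default 1.06).
#' @return Mass in grams.
#' @export
tissue_mass <- function(voxel_count, voxel_volume_mm3,
                        density_g_per_ml = 1.06) {
  stopifnot(all(voxel_count >= 0), all(voxel_volume_mm3 >= 0))
  voxel_count * voxel_volume_mm3 * 1e-3 * density_g_per_ml
}

#' Contrast-to-noise ratio
#'
#' Difference between infarcted and remote myocardial mean signal intensity
#' normalized by the noise level.
#'
#' @param image Numeric array.
#' @param infarct_mask,remote_mask Non-empty disjoint logical arrays.
#' @param noise_sigma Positive noise level in signal units.
#' @return Dimensionless CNR.
#' @export
cnr <- function(image, infarct_mask, remote_mask, noise_sigma) {
  if (!is.numeric(noise_sigma) || noise_sigma <= 0) {
    stop("`noise_sigma` must be positive")
  }
  if (!any(infarct_mask) || !any(remote_mask)) {
    stop("masks must be non-empty")
  }
  if (any(infarct_mask & remote_mask)) stop("masks must be disjoint")
  (mean(image[infarct_mask]) - mean(image[remote_mask])) / noise_sigma
}

#' Estimate the noise level from a background region
#'
#' Gaussian model: standard deviation of the background samples. Rician
#' model: in signal-free background the magnitude is Rayleigh-distributed
#' with mean `sigma * sqrt(pi / 2)`, so sigma is the background mean divided
#' by `sqrt(pi / 2)`.
#'
#' @param image Numeric array.
#' @param background_mask Non-empty logical array outside the body.
#' @param model `"rician"` or `"gaussian"`.
#' @return Estimated sigma in signal units.
#' @export
estimate_noise <- function(image, background_mask,
                           model = c("rician", "gaussian")) {
  model <- match.arg(model)
  v <- image[background_mask]
  if (!length(v)) stop("background mask is empty")
  if (all(v == 0)) {
    warning("background is identically zero; sigma = 0")
    return(0)
  }
  if (model == "gaussian") stats::sd(v) else mean(v) / sqrt(pi / 2)
}
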