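#' Closed counterclockwise circle polygon
#'
#' @param center Numeric pair, 0-based pixel-centre coordinates.
#' @param radius Radius in pixel units.
#' @param n Number of vertices.
#' @return `(n + 1) x 2` matrix; last vertex repeats the first.
#' @export
circle_polygon <- function(center, radius, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  v <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  rbind(v, v[1, , drop = FALSE])
}

# drop a repeated closing vertex if present
open_polygon <- function(poly) {
  n <- nrow(poly)
  if (n > 1L && all(abs(poly[1, ] - poly[n, ]) < 1e-12)) {
    poly[-n, , drop = FALSE]
  } else {
    poly
  }
}

# signed shoelace area (positive for counterclockwise vertex order)
polygon_area <- function(poly) {
  v <- open_polygon(poly)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# shoelace area centroid
polygon_centroid <- function(poly) {
  v <- open_polygon(poly)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) stop("degenerate polygon: area is ~0")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Cardiac centroid of a contour pair
#'
#' The area centroid of the epicardial polygon, about which wedges and radial
#' sections are constructed.
#'
#' @param contours List with elements `epicardial` and `endocardial` (ordered
#'   closed polygons, 0-based pixel-centre coordinates).
#' @return Numeric pair `(x, y)`.
#' @export
cardiac_centroid <- function(contours) {
  polygon_centroid(contours$epicardial)
}

# piecewise-linear radius-vs-angle profile of a star-shaped polygon about a
# centre point; returns a function of angle in degrees
polygon_radius_fun <- function(poly, center) {
  v <- open_polygon(poly)
  dx <- v[, 1] - center[1]; dy <- v[, 2] - center[2]
  th <- (atan2(dy, dx) * 180 / pi) %% 360
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # wrap for interpolation across 0/360
  th_ext <- c(th[length(th)] - 360, th, th[1] + 360)
  r_ext <- c(r[length(r)], r, r[1])
  function(angle) {
    stats::approx(th_ext, r_ext, xout = angle %% 360, rule = 2)$y
  }
}

#' Build the chord grid
#'
#' Assigns every masked myocardial pixel of every slice to one of `n_wedges`
#' circumferential wedges (by polar angle about the cardiac centroid,
#' counterclockwise from `reference_angle`) and one of `n_radial` radial
#' sections (by normalized transmural depth along the centroid ray between the
#' endocardial and epicardial contours; section 1 is subendocardial). Depth
#' `d` maps to section `floor(n_radial * d) + 1`, with `d = 1` clamped into
#' the outermost section. Pixels whose ray does not usefully intersect both
#' contours (depth far outside `[0, 1]`) are clamped to the nearest section
#' and counted in `n_fallback`.
#'
#' @param contours Per-slice list of contour pairs (as in a `ground_truth`),
#'   or a single contour pair applied to every slice.
#' @param mask Logical array `[x, y, slice]` of myocardial pixels.
#' @param n_wedges,n_radial Grid dimensions (defaults 20 and 5).
#' @param reference_angle Start angle of wedge 1, degrees counterclockwise
#'   from +x.
#' @return Object of class `chord_grid` with integer arrays `wedge` and
#'   `radial` (NA outside the mask), per-slice `centroid`, and bookkeeping.
#' @export
build_chord_grid <- function(contours, mask, n_wedges = 20L, n_radial = 5L,
                             reference_angle = 0) {
  stopifnot(length(dim(mask)) == 3L, n_wedges >= 1L, n_radial >= 1L)
  nx <- dim(mask)[1]; ny <- dim(mask)[2]; nz <- dim(mask)[3]
  if (!is.null(contours$epicardial)) {
    contours <- rep(list(contours), nz)
  }
  wedge <- array(NA_integer_, dim = dim(mask))
  radial <- array(NA_integer_, dim = dim(mask))
  depth_arr <- array(NA_real_, dim = dim(mask))
  angle_arr <- array(NA_real_, dim = dim(mask))
  centroids <- matrix(NA_real_, nz, 2)
  n_fallback <- 0L
  wedge_width <- 360 / n_wedges

  for (z in seq_len(nz)) {
    sl <- mask[, , z]
    if (!any(sl)) next
    cp <- contours[[z]]
    if (is.null(cp)) stop("no contours for slice ", z)
    ctr <- cardiac_centroid(cp)
    centroids[z, ] <- ctr
    r_endo <- polygon_radius_fun(cp$endocardial, ctr)
    r_epi <- polygon_radius_fun(cp$epicardial, ctr)

    idx <- which(sl)
    px <- (idx - 1L) %% nx          # 0-based x index
    py <- (idx - 1L) %/% nx         # 0-based y index
    dx <- px - ctr[1]; dy <- py - ctr[2]
    th <- (atan2(dy, dx) * 180 / pi) %% 360
    r <- sqrt(dx^2 + dy^2)
    re <- r_endo(th); rp <- r_epi(th)
    d <- (r - re) / (rp - re)
    bad <- !is.finite(d) | rp <= re | d < -0.02 | d > 1.02
    n_fallback <- n_fallback + sum(bad)
    d <- pmin(pmax(d, 0), 1 - 1e-9)

    w <- floor(((th - reference_angle) %% 360) / wedge_width) + 1L
    w <- pmin(as.integer(w), n_wedges)
    s <- as.integer(floor(n_radial * d) + 1L)

    wz <- wedge[, , z]; rz <- radial[, , z]
    dz <- depth_arr[, , z]; az <- angle_arr[, , z]
    wz[idx] <- w; rz[idx] <- s; dz[idx] <- d; az[idx] <- th
    wedge[, , z] <- wz; radial[, , z] <- rz
    depth_arr[, , z] <- dz; angle_arr[, , z] <- az
  }

  structure(list(wedge = wedge, radial = radial, depth = depth_arr,
                 angle = angle_arr, mask = mask, centroid = centroids,
                 n_wedges = as.integer(n_wedges),
                 n_radial = as.integer(n_radial),
                 reference_angle = reference_angle,
                 n_fallback = n_fallback),
            class = "chord_grid")
}

#' Per-sector signal table
#'
#' Mean image signal per (slice, wedge, radial section), normalized to the
#' table maximum, plus a mid-myocardial summary restricted to radial sections
#' 2-4 (again normalized to its own maximum). Empty sectors are simply absent
#' from the table and excluded from the normalization maximum.
#'
#' @param grid A [build_chord_grid()] result.
#' @param image Numeric array matching the grid geometry.
#' @return Object of class `sector_table`: list of data frames `sectors`
#'   (slice, wedge, radial, n, mean, normalized) and `mid_myocardium`
#'   (slice, wedge, n, mean, normalized).
#' @export
sector_signal <- function(grid, image) {
  stopifnot(inherits(grid, "chord_grid"),
            all(dim(image) == dim(grid$mask)))
  idx <- which(grid$mask)
  slice <- (idx - 1L) %/% (dim(grid$mask)[1] * dim(grid$mask)[2]) + 1L
  df <- data.frame(slice = slice,
                   wedge = grid$wedge[idx],
                   radial = grid$radial[idx],
                   value = image[idx])
  agg <- stats::aggregate(value ~ slice + wedge + radial, data = df,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ slice + wedge + radial, data = df,
                          FUN = length)
  sectors <- data.frame(slice = agg$slice, wedge = agg$wedge,
                        radial = agg$radial, n = cnt$value, mean = agg$value)
  sectors$normalized <- sectors$mean / max(sectors$mean)
  sectors <- sectors[order(sectors$slice, sectors$wedge, sectors$radial), ]
  rownames(sectors) <- NULL

  mid_df <- df[df$radial >= 2 & df$radial <= 4, ]
  if (nrow(mid_df)) {
    magg <- stats::aggregate(value ~ slice + wedge, data = mid_df, FUN = mean)
    mcnt <- stats::aggregate(value ~ slice + wedge, data = mid_df,
                             FUN = length)
    mid <- data.frame(slice = magg$slice, wedge = magg$wedge, n = mcnt$value,
                      mean = magg$value)
    mid$normalized <- mid$mean / max(mid$mean)
    mid <- mid[order(mid$slice, mid$wedge), ]
    rownames(mid) <- NULL
  } else {
    mid <- data.frame(slice = integer(), wedge = integer(), n = integer(),
                      mean = numeric(), normalized = numeric())
  }
  structure(list(sectors = sectors, mid_myocardium = mid),
            class = "sector_table")
}
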