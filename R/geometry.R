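#  Layer geometry: midventricular-line construction and endo/epi layer
#  assignment on interpolated pixel-wise MBF maps.
#
#  Grid convention: `values[i, j]` has its pixel centre at
#  x = (j - 0.5) * spacing[2], y = (i - 0.5) * spacing[1] (mm), origin at the
#  outer corner of pixel (1, 1). Rows advance along y, columns along x.

#' Pixel-wise perfusion map
#'
#' A single short-axis slice of a quantitative MBF map in mL/min/g.
#' Non-myocardial pixels carry `NA`, the package's background sentinel:
#' arithmetic with a stray background pixel propagates loudly instead of
#' silently biasing a mean.
#'
#' @param values numeric matrix of MBF values (mL/min/g); `NA` = background.
#' @param spacing pixel spacing in mm, length 1 (isotropic) or 2 (row, col).
#' @param slice one of `"basal"`, `"mid"`, `"apical"`.
#' @param state one of `"stress"`, `"rest"`.
#' @return an object of class `perfusion_map`.
#' @export
perfusion_map <- function(values, spacing,
                          slice = c("basal", "mid", "apical"),
                          state = c("stress", "rest")) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0) {
    stop_tp("`values` must be a non-empty numeric matrix")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_tp("MBF values must be >= 0 (background pixels are NA)")
  }
  spacing <- rep_len(as.numeric(spacing), 2L)
  check_number(spacing, "spacing", positive = TRUE, len = 2L)
  slice <- match.arg(slice)
  state <- match.arg(state)
  structure(list(values = values, spacing = spacing,
                 slice = slice, state = state),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  cat(sprintf("<perfusion_map> %s/%s %dx%d @ %.3gx%.3g mm, %d myocardial pixels\n",
              x$state, x$slice, nrow(x$values), ncol(x$values),
              x$spacing[1], x$spacing[2], sum(!is.na(x$values))))
  invisible(x)
}

#  Pixel-centre coordinate axes of a map (mm).
map_axes <- function(map) {
  list(x = (seq_len(ncol(map$values)) - 0.5) * map$spacing[2],
       y = (seq_len(nrow(map$values)) - 0.5) * map$spacing[1])
}

#  Physical extent (x, y) in mm.
map_extent <- function(map) {
  c(ncol(map$values) * map$spacing[2], nrow(map$values) * map$spacing[1])
}

#' Resample a perfusion map to a target pixel spacing
#'
#' Bilinear interpolation on pixel centres; the physical extent of the grid is
#' preserved (new pixel count = extent / target spacing, rounded). Background
#' `NA` pixels are excluded from the interpolation support: where bilinear
#' interpolation would mix in a background neighbour, the value of the nearest
#' source pixel is used instead, so the background sentinel never bleeds into
#' the myocardium (and vice versa the myocardium never bleeds outward).
#'
#' @param map a [perfusion_map()].
#' @param target_spacing target isotropic spacing in mm (default 1).
#' @return a [perfusion_map()] at the target spacing.
#' @export
interpolate_map <- function(map, target_spacing = 1.0) {
  stopifnot(inherits(map, "perfusion_map"))
  check_number(target_spacing, "target_spacing", positive = TRUE)
  ext <- map_extent(map)
  if (target_spacing >= min(ext)) {
    stop_tp("target_spacing (%.3g mm) is not smaller than the map extent (%.3g x %.3g mm)",
            target_spacing, ext[1], ext[2])
  }
  ax <- map_axes(map)
  n_col <- max(2L, as.integer(round(ext[1] / target_spacing)))
  n_row <- max(2L, as.integer(round(ext[2] / target_spacing)))
  xq <- (seq_len(n_col) - 0.5) * target_spacing
  yq <- (seq_len(n_row) - 0.5) * target_spacing
  # clamp queries to the source pixel-centre hull (edge padding)
  xqc <- pmin(pmax(xq, ax$x[1]), ax$x[length(ax$x)])
  yqc <- pmin(pmax(yq, ax$y[1]), ax$y[length(ax$y)])
  grid <- expand.grid(x = xqc, y = yqc)
  z <- pracma::interp2(ax$x, ax$y, map$values, grid$x, grid$y, method = "linear")
  # NA fallback: nearest source pixel (keeps myocardial support intact next
  # to the background boundary)
  miss <- is.na(z)
  if (any(miss)) {
    ci <- pmin(pmax(round(grid$x[miss] / map$spacing[2] + 0.5), 1), ncol(map$values))
    ri <- pmin(pmax(round(grid$y[miss] / map$spacing[1] + 0.5), 1), nrow(map$values))
    z[miss] <- map$values[cbind(ri, ci)]
  }
  out <- matrix(z, nrow = n_row, ncol = n_col, byrow = TRUE)
  perfusion_map(out, target_spacing, slice = map$slice, state = map$state)
}

#' Uniform ray directions
#'
#' Unit direction vectors at uniform angular increments, counter-clockwise
#' from the +x axis. The default 360 rays give the 1-degree increment used to
#' construct the midventricular line.
#'
#' @param n_rays number of rays (>= 8).
#' @return `n_rays` x 2 matrix of unit vectors with an `angles_deg` attribute.
#' @export
cast_rays <- function(n_rays = 360) {
  if (!is.numeric(n_rays) || length(n_rays) != 1 || n_rays < 8 ||
      n_rays != round(n_rays)) {
    stop_tp("`n_rays` must be an integer >= 8")
  }
  th <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  structure(cbind(cos(th), sin(th)), angles_deg = (seq_len(n_rays) - 1) * 360 / n_rays)
}

#  Distance from `center` along each unit direction to the unique crossing of
#  `poly`. Errors (naming the ray angle) if a ray does not cross exactly once:
#  severely non-star-shaped contours are rejected rather than silently
#  mis-split.
ray_contour_distance <- function(center, rays, poly, what = "contour") {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  a <- poly
  d <- poly[c(2:n, 1), , drop = FALSE] - poly
  wx <- a[, 1] - center[1]
  wy <- a[, 2] - center[2]
  angles <- attr(rays, "angles_deg") %||% (atan2(rays[, 2], rays[, 1]) * 180 / pi)
  out <- numeric(nrow(rays))
  for (k in seq_len(nrow(rays))) {
    ux <- rays[k, 1]; uy <- rays[k, 2]
    denom <- ux * d[, 2] - uy * d[, 1]
    s <- (uy * wx - ux * wy) / denom            # position along the edge
    t <- (wx * d[, 2] - wy * d[, 1]) / -denom   # distance along the ray
    hit <- is.finite(s) & s > -1e-9 & s < 1 + 1e-9 & t > 1e-9
    # a ray through a shared vertex touches two adjacent edges at the same
    # distance; merge crossings closer than 1e-6 mm along the ray
    ts <- sort(t[hit])
    if (length(ts) > 1) ts <- ts[c(TRUE, diff(ts) > 1e-6)]
    if (length(ts) != 1L) {
      stop_tp("ray at %.1f deg crosses the %s %d times (expected exactly once)",
              angles[k], what, length(ts), class = "tp_error_geometry")
    }
    out[k] <- ts
  }
  out
}

#' Midventricular line
#'
#' Constructs the closed midline polyline that splits the wall into
#' endocardial and epicardial layers: rays are cast from the blood-pool
#' centre at uniform angular increments; on each ray the midline vertex is
#' the midpoint between the ray's endocardial and epicardial border
#' crossings (equidistant from the two contours along the ray).
#'
#' @param contours a [contour_set()].
#' @param n_rays number of rays (default 360, i.e. 1-degree increments).
#' @param center optional override of the blood-pool centre (mm).
#' @return `n_rays` x 2 matrix of midline vertices (closed implicitly), with
#'   attributes `r_endo`, `r_epi` (per-ray border distances), `center` and
#'   `angles_deg`.
#' @export
compute_midline <- function(contours, n_rays = 360, center = NULL) {
  stopifnot(inherits(contours, "contour_set"))
  rays <- if (is.matrix(n_rays)) n_rays else cast_rays(n_rays)
  center <- center %||% blood_pool_center(contours)
  r_endo <- ray_contour_distance(center, rays, contours$endo, "endocardial contour")
  r_epi <- ray_contour_distance(center, rays, contours$epi, "epicardial contour")
  if (any(r_epi <= r_endo)) {
    stop_tp("epicardial crossing closer than endocardial crossing at %.1f deg",
            (attr(rays, "angles_deg"))[which(r_epi <= r_endo)[1]],
            class = "tp_error_geometry")
  }
  r_mid <- (r_endo + r_epi) / 2
  mid <- cbind(center[1] + r_mid * rays[, 1], center[2] + r_mid * rays[, 2])
  structure(mid, r_endo = r_endo, r_epi = r_epi, center = center,
            angles_deg = attr(rays, "angles_deg"))
}

#' Assign endocardial and epicardial layer masks
#'
#' Labels each pixel of an (interpolated) map by pixel-centre point-in-polygon
#' tests: myocardium = inside the epicardial contour and not inside the
#' endocardial contour; a myocardial pixel belongs to the endocardial layer
#' when its centre lies inside the midline polygon, otherwise to the
#' epicardial layer. The two layers always partition the myocardium exactly.
#'
#' @param map a [perfusion_map()], typically after [interpolate_map()].
#' @param contours a [contour_set()] in the same mm frame as the map.
#' @param midline optional precomputed [compute_midline()] result; computed
#'   with default settings when missing.
#' @return an object of class `layer_masks`: logical matrices `myocardium`,
#'   `endo_layer`, `epi_layer` plus the `midline` and grid metadata.
#' @export
assign_layers <- function(map, contours, midline = NULL) {
  stopifnot(inherits(map, "perfusion_map"), inherits(contours, "contour_set"))
  if (is.null(midline)) midline <- compute_midline(contours)
  ax <- map_axes(map)
  g <- expand.grid(x = ax$x, y = ax$y)   # column-major over x then y
  in_epi <- point_in_polygon(g$x, g$y, contours$epi)
  in_endo <- point_in_polygon(g$x, g$y, contours$endo)
  myo_v <- in_epi & !in_endo
  if (!any(myo_v)) {
    stop_tp("empty myocardium mask: contours do not cover any pixel centre",
            class = "tp_error_geometry")
  }
  in_mid <- logical(length(myo_v))
  in_mid[myo_v] <- point_in_polygon(g$x[myo_v], g$y[myo_v], midline)
  shape <- function(v) t(matrix(v, nrow = ncol(map$values), ncol = nrow(map$values)))
  myocardium <- shape(myo_v)
  endo_layer <- shape(myo_v & in_mid)
  structure(list(myocardium = myocardium,
                 endo_layer = endo_layer,
                 epi_layer = myocardium & !endo_layer,
                 midline = midline,
                 spacing = map$spacing,
                 dim = dim(map$values),
                 center = attr(midline, "center")),
            class = "layer_masks")
}

#' @export
print.layer_masks <- function(x, ...) {
  cat(sprintf("<layer_masks> %dx%d grid: %d myocardial pixels (%d endo / %d epi)\n",
              x$dim[1], x$dim[2], sum(x$myocardium),
              sum(x$endo_layer), sum(x$epi_layer)))
  invisible(x)
}
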