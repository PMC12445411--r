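#  Contour polygons: construction, validation and basic computational
#  geometry. All coordinates are continuous millimetres with the origin at
#  the outer corner of pixel (1, 1); polygons are n x 2 matrices (x, y),
#  open (last vertex not repeated).

#' Polygon area (shoelace formula)
#'
#' @param poly numeric n x 2 matrix of vertices (mm), open.
#' @param signed if `TRUE` return the signed area (positive for
#'   counter-clockwise vertex order).
#' @return area in mm^2.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  a <- sum(x * ys - xs * y) / 2
  if (signed) a else abs(a)
}

#' Polygon area centroid
#'
#' Centroid of the enclosed region (not the vertex average), by the standard
#' shoelace moment formula.
#'
#' @inheritParams polygon_area
#' @return length-2 numeric (x, y) in mm.
#' @export
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    stop_tp("degenerate polygon: area is zero", class = "tp_error_geometry")
  }
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Test points against a polygon
#'
#' Even-odd rule, vectorised in compiled code. Points exactly on the boundary
#' follow the crossing-number convention (a measure-zero set on pixel grids).
#'
#' @param x,y point coordinates (mm).
#' @param poly polygon matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  points_in_polygon(as.numeric(x), as.numeric(y), poly[, 1], poly[, 2])
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2 || nrow(poly) < 3 || anyNA(poly)) {
    stop_tp("polygon must be a numeric n x 2 matrix with n >= 3 and no NA",
            class = "tp_error_geometry")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (all(abs(poly[1, ] - poly[n, ]) < 1e-12)) poly <- poly[-n, , drop = FALSE]
  unname(poly)
}

#  Simplicity check: no two non-adjacent edges intersect. O(V^2) vectorised
#  orientation tests; returns the index of an offending vertex for messages.
polygon_simple_violation <- function(poly) {
  n <- nrow(poly)
  a1 <- poly
  a2 <- poly[c(2:n, 1), , drop = FALSE]
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$j > idx$i + 1 & !(idx$i == 1 & idx$j == n), , drop = FALSE]
  if (nrow(idx) == 0) return(NA_integer_)
  p1 <- a1[idx$i, , drop = FALSE]; p2 <- a2[idx$i, , drop = FALSE]
  q1 <- a1[idx$j, , drop = FALSE]; q2 <- a2[idx$j, , drop = FALSE]
  orient <- function(a, b, c) {
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  }
  d1 <- orient(p1, p2, q1); d2 <- orient(p1, p2, q2)
  d3 <- orient(q1, q2, p1); d4 <- orient(q1, q2, p2)
  hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(hit)) idx$i[which(hit)[1]] else NA_integer_
}

#' Contour set for one short-axis slice
#'
#' Bundles the endocardial and epicardial border polygons with the
#' right-ventricular (RV) insertion landmark. Validates that both polygons are
#' simple, that the endocardial contour lies strictly inside the epicardial
#' one, and derives the blood-pool centre (endocardial area centroid).
#'
#' @param endo,epi polygons (n x 2 matrices, mm), endo strictly inside epi.
#' @param rv_insertion length-2 point (mm) on or near the epicardial contour,
#'   marking the anterior RV insertion; may be `NULL` if parcellation is not
#'   needed.
#' @return an object of class `contour_set`.
#' @export
contour_set <- function(endo, epi, rv_insertion = NULL) {
  endo <- as_polygon(endo)
  epi <- as_polygon(epi)
  for (nm in c("endo", "epi")) {
    v <- polygon_simple_violation(get(nm))
    if (!is.na(v)) {
      stop_tp("%s contour is self-intersecting near vertex %d", nm, v,
              class = "tp_error_geometry")
    }
  }
  if (!all(point_in_polygon(endo[, 1], endo[, 2], epi))) {
    stop_tp("endocardial contour is not strictly inside the epicardial contour",
            class = "tp_error_geometry")
  }
  if (!is.null(rv_insertion)) {
    check_number(rv_insertion, "rv_insertion", len = 2L)
    rv_insertion <- as.numeric(rv_insertion)
  }
  center <- polygon_centroid(endo)
  if (!point_in_polygon(center[1], center[2], endo)) {
    stop_tp("blood-pool centre falls outside the endocardial contour",
            class = "tp_error_geometry")
  }
  structure(list(endo = endo, epi = epi, rv_insertion = rv_insertion,
                 blood_pool_center = center),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> endo %d vertices, epi %d vertices, centre (%.2f, %.2f) mm%s\n",
              nrow(x$endo), nrow(x$epi), x$blood_pool_center[1],
              x$blood_pool_center[2],
              if (is.null(x$rv_insertion)) ", no RV insertion" else ""))
  invisible(x)
}

#' Blood-pool centre
#'
#' The centre of the LV blood pool, defined as the area centroid of the
#' endocardial polygon (robust and deterministic; always inside the contour
#' for star-shaped LV borders).
#'
#' @param contours a [contour_set()].
#' @return length-2 numeric (x, y) in mm.
#' @export
blood_pool_center <- function(contours) {
  stopifnot(inherits(contours, "contour_set"))
  contours$blood_pool_center
}

#' Circle and ellipse contour polygons
#'
#' Convenience constructors used by the phantom generator and tests.
#'
#' @param center length-2 point (mm).
#' @param radius scalar radius, or length-2 semi-axes `(a, b)` for
#'   `ellipse_contour()`.
#' @param n number of vertices.
#' @return n x 2 polygon matrix.
#' @export
circle_contour <- function(center, radius, n = 360) {
  ellipse_contour(center, c(radius, radius), n)
}

#' @rdname circle_contour
#' @export
ellipse_contour <- function(center, radius, n = 360) {
  check_number(center, "center", len = 2L)
  radius <- rep_len(as.numeric(radius), 2L)
  check_number(radius, "radius", positive = TRUE, len = 2L)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius[1] * cos(th), center[2] + radius[2] * sin(th))
}
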