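#' Closed cell-boundary polygons
#'
#' A `boundary_polygon` is the common currency between the vertex-model
#' simulator and the shape-metric layer: an ordered loop of 2-D vertex
#' positions (micrometres) describing the basal outline of one cell at one
#' time point. Polygons are closed by convention (the last vertex connects
#' back to the first) and are stored counter-clockwise; clockwise input is
#' reversed on construction.
#'
#' @param vertices numeric matrix with two columns (x, y) in micrometres,
#'   one row per vertex, at least three rows.
#' @param frame_time acquisition/simulation time in minutes.
#' @param cell_id identifier of the cell the outline belongs to.
#' @return an object of class `boundary_polygon`: the vertex matrix with
#'   attributes `frame_time` and `cell_id`.
#' @examples
#' sq <- boundary_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' polygon_measures(sq)$area
#' @export
boundary_polygon <- function(vertices, frame_time = 0, cell_id = "cell") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix")
  if (nrow(vertices) < 3L) stop("a boundary polygon needs at least 3 vertices")
  storage.mode(vertices) <- "double"
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  d <- vertices - vertices[c(2:nrow(vertices), 1L), , drop = FALSE]
  if (any(rowSums(d^2) == 0)) stop("duplicated consecutive vertices")
  a <- signed_area(vertices)
  if (a == 0) stop("degenerate polygon: zero signed area")
  if (a < 0) vertices <- vertices[nrow(vertices):1, , drop = FALSE]
  structure(vertices,
            frame_time = as.numeric(frame_time),
            cell_id = cell_id,
            class = c("boundary_polygon", "matrix", "array"))
}

#' @export
print.boundary_polygon <- function(x, ...) {
  cat(sprintf("<boundary_polygon> cell %s, t = %g min, %d vertices\n",
              attr(x, "cell_id"), attr(x, "frame_time"), nrow(x)))
  invisible(x)
}

#' @rdname boundary_polygon
#' @param x object to test.
#' @export
is_boundary_polygon <- function(x) inherits(x, "boundary_polygon")

# signed shoelace area; > 0 for counter-clockwise loops
signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

as_poly_matrix <- function(poly) {
  if (is_boundary_polygon(poly)) return(unclass(poly)[, , drop = FALSE])
  boundary_polygon(poly)
}

#' Tissue axis frame
#'
#' Fixes the anatomical axes in the image/simulation plane: `ap_unit` points
#' from anterior to posterior, `dv_unit` is orthogonal (dorsal-ventral). All
#' orientation-valued outputs (ruffle angles, fiber polarity) are reported
#' relative to this frame. The default puts A-P along +x and D-V along +y.
#'
#' @param ap_unit length-2 numeric, direction anterior -> posterior.
#' @param dv_unit length-2 numeric orthogonal to `ap_unit`; by default
#'   `ap_unit` rotated +90 degrees.
#' @export
axis_frame <- function(ap_unit = c(1, 0), dv_unit = NULL) {
  ap_unit <- ap_unit / sqrt(sum(ap_unit^2))
  if (is.null(dv_unit)) dv_unit <- c(-ap_unit[2], ap_unit[1])
  dv_unit <- dv_unit / sqrt(sum(dv_unit^2))
  if (abs(sum(ap_unit * dv_unit)) > 1e-9)
    stop("ap_unit and dv_unit must be orthogonal")
  structure(list(ap_unit = ap_unit, dv_unit = dv_unit), class = "axis_frame")
}

#' Basic polygon measurements
#'
#' Area (shoelace), perimeter (closed polyline length), equivdiameter and the
#' area centroid of a closed cell outline. The equivdiameter is the mean
#' distance between the cell centre and its boundary vertices; for ruffled
#' outlines this is well-defined where a max- or min-radius reading is not.
#'
#' @param poly a [boundary_polygon()] (or an n x 2 coordinate matrix).
#' @return list with `area` (um^2), `perimeter` (um), `equivdiameter` (um)
#'   and `centroid` (length-2 numeric, um).
#' @examples
#' hexv <- t(sapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3))))
#' polygon_measures(boundary_polygon(hexv))$area   # 3*sqrt(3)/2
#' @export
polygon_measures <- function(poly) {
  v <- as_poly_matrix(poly)
  n <- nrow(v)
  j <- c(2:n, 1L)
  cross <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  area <- sum(cross) / 2
  if (area <= 0) stop("degenerate polygon: non-positive area")
  per <- sum(sqrt(rowSums((v[j, , drop = FALSE] - v)^2)))
  cx <- sum((v[, 1] + v[j, 1]) * cross) / (6 * area)
  cy <- sum((v[, 2] + v[j, 2]) * cross) / (6 * area)
  eqd <- mean(sqrt((v[, 1] - cx)^2 + (v[, 2] - cy)^2))
  list(area = area, perimeter = per, equivdiameter = eqd, centroid = c(cx, cy))
}

#' Signed discrete curvature along a cell boundary
#'
#' Per-vertex signed curvature (1/um) of a closed outline, positive on
#' convex (outward-protruding) arcs of a counter-clockwise polygon -- the
#' sign convention used to call membrane ruffles. Vertex positions are first
#' window-averaged along the loop, then the curvature at vertex i is the
#' inverse circumradius of the triangle (i-h, i, i+h) (Menger curvature)
#' with h = max(1, (smooth_window - 1) / 2), signed by the local turn.
#'
#' @param poly a [boundary_polygon()].
#' @param smooth_window odd positive vertex count used to smooth positions
#'   before estimation; 1 disables smoothing.
#' @return numeric vector, one signed curvature per vertex (1/um).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' circ <- boundary_polygon(5 * cbind(cos(th), sin(th)))
#' mean(discrete_curvature(circ))  # ~ 0.2
#' @export
discrete_curvature <- function(poly, smooth_window = 1L) {
  v <- as_poly_matrix(poly)
  n <- nrow(v)
  if (n < 5L) stop("curvature needs at least 5 vertices")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be odd and >= 1")
  if (smooth_window >= n) stop("smooth_window must be smaller than the vertex count")
  if (smooth_window > 1L) {
    half <- (smooth_window - 1L) %/% 2L
    idx <- outer(seq_len(n), (-half):half, function(i, k) ((i - 1 + k) %% n) + 1)
    v <- cbind(rowMeans(matrix(v[idx, 1], n)), rowMeans(matrix(v[idx, 2], n)))
  }
  h <- max(1L, (smooth_window - 1L) %/% 2L)
  ip <- ((seq_len(n) - 1 - h) %% n) + 1
  im <- ((seq_len(n) - 1 + h) %% n) + 1
  a <- v - v[ip, , drop = FALSE]          # incoming chord
  b <- v[im, , drop = FALSE] - v          # outgoing chord
  cvec <- v[im, , drop = FALSE] - v[ip, , drop = FALSE]
  cr <- a[, 1] * b[, 2] - a[, 2] * b[, 1] # 2 * signed triangle area
  la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(cvec^2))
  denom <- la * lb * lc
  kappa <- ifelse(denom > 0, 2 * cr / denom, 0)
  as.numeric(kappa)
}

#' Outward unit normal at a boundary vertex
#'
#' Unit vector perpendicular to the local tangent (central difference of the
#' two neighbouring vertices), pointing away from the polygon interior. For
#' a counter-clockwise loop this is the tangent rotated by -90 degrees.
#'
#' @param poly a [boundary_polygon()].
#' @param vertex_index integer index (1-based), or a vector of indices.
#' @return length-2 unit vector, or an n x 2 matrix when several indices are
#'   requested.
#' @export
outward_normal <- function(poly, vertex_index = seq_len(nrow(as_poly_matrix(poly)))) {
  v <- as_poly_matrix(poly)
  n <- nrow(v)
  i <- as.integer(vertex_index)
  if (any(i < 1L | i > n)) stop("vertex_index out of range")
  ip <- ((i - 2) %% n) + 1
  im <- (i %% n) + 1
  t_ <- v[im, , drop = FALSE] - v[ip, , drop = FALSE]
  nor <- cbind(t_[, 2], -t_[, 1])
  len <- sqrt(rowSums(nor^2))
  if (any(len == 0)) stop("undefined normal: coincident neighbouring vertices")
  nor <- nor / len
  if (length(i) == 1L) as.numeric(nor) else nor
}
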