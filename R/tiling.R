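#' Tissue mesh: cells as loops over a shared vertex pool
#'
#' The modified vertex model stores many boundary vertices per cell (one per
#' E-cadherin cluster) in a single shared pool; each cell is an ordered,
#' counter-clockwise loop of pool indices, and vertices on an edge shared by
#' two neighbouring cells are referenced by both loops rather than
#' duplicated. Every vertex additionally carries a substrate anchor: the
#' extracellular-matrix point its focal adhesion is attached to.
#'
#' @param vertex_pool n x 2 numeric matrix of vertex positions (um).
#' @param cells list of integer vectors, each an ordered CCW index loop.
#' @param anchors n x 2 numeric matrix of substrate anchor positions; by
#'   default the vertex positions themselves.
#' @return object of class `tissue_mesh` with fields `pool`, `cells`,
#'   `anchors` and `adjacency` (list: cells touching each vertex).
#' @seealso [hexagonal_tiling()]
#' @export
tissue_mesh <- function(vertex_pool, cells, anchors = vertex_pool) {
  vertex_pool <- as.matrix(vertex_pool)
  anchors <- as.matrix(anchors)
  stopifnot(ncol(vertex_pool) == 2L, identical(dim(vertex_pool), dim(anchors)))
  cells <- lapply(cells, as.integer)
  n <- nrow(vertex_pool)
  for (loop in cells) {
    if (length(loop) < 3L || any(loop < 1L | loop > n) || anyDuplicated(loop))
      stop("each cell must be a loop of >= 3 distinct pool indices")
    if (signed_area(vertex_pool[loop, , drop = FALSE]) <= 0)
      stop("cell loops must be counter-clockwise with positive area")
  }
  adjacency <- vector("list", n)
  for (ci in seq_along(cells))
    for (vi in cells[[ci]]) adjacency[[vi]] <- c(adjacency[[vi]], ci)
  structure(list(pool = vertex_pool, cells = cells,
                 anchors = anchors, adjacency = adjacency),
            class = "tissue_mesh")
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %d cells, %d shared vertices\n",
              length(x$cells), nrow(x$pool)))
  invisible(x)
}

#' Extract one cell of a mesh as a boundary polygon
#'
#' @param mesh a [tissue_mesh()].
#' @param cell integer cell index.
#' @param frame_time time stamp to attach (min).
#' @export
mesh_cell_polygon <- function(mesh, cell, frame_time = 0) {
  loop <- mesh$cells[[cell]]
  boundary_polygon(mesh$pool[loop, , drop = FALSE],
                   frame_time = frame_time, cell_id = cell)
}

#' Hexagonally tiled initial epithelium
#'
#' Builds the initial condition of the simulations: `n_rows` x `n_cols`
#' tightly packed regular hexagons (flat-topped, edge length `edge_len` um)
#' whose edges are subdivided so that each edge carries `verts_per_edge`
#' vertices -- the "many vertices per cell" modification that lets the model
#' resolve membrane ruffles. Vertices on shared edges are pooled, so
#' neighbouring cells reference identical indices, and substrate anchors
#' start at the vertex positions.
#'
#' @param n_rows,n_cols patch size in cells (>= 1). Columns run along the
#'   A-P (x) axis.
#' @param edge_len hexagon edge length in um.
#' @param verts_per_edge vertices carried by each hexagon edge (the shared
#'   corner plus `verts_per_edge - 1` interior points); >= 1.
#' @return a [tissue_mesh()].
#' @examples
#' m <- hexagonal_tiling(1, 1, 1, 1)
#' polygon_measures(mesh_cell_polygon(m, 1))$area  # 3*sqrt(3)/2
#' @export
hexagonal_tiling <- function(n_rows, n_cols, edge_len = 1, verts_per_edge = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  verts_per_edge <- as.integer(verts_per_edge)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (edge_len <= 0) stop("edge_len must be positive")
  if (verts_per_edge < 1L) stop("verts_per_edge must be >= 1")

  # flat-top hexagon corners, CCW starting at angle 0
  corner <- t(sapply(0:5, function(k) edge_len * c(cos(k * pi / 3), sin(k * pi / 3))))
  key_of <- function(p) paste(round(p[1] / edge_len, 9), round(p[2] / edge_len, 9))

  pool <- matrix(numeric(0), 0, 2)
  keys <- character(0)
  index <- new.env(parent = emptyenv())
  cells <- vector("list", n_rows * n_cols)
  ci <- 0L
  for (col in seq_len(n_cols) - 1L) {
    for (row in seq_len(n_rows) - 1L) {
      centre <- c(1.5 * edge_len * col,
                  sqrt(3) * edge_len * row + (col %% 2L) * sqrt(3) * edge_len / 2)
      loop <- integer(0)
      for (k in 1:6) {
        a <- corner[k, ]; b <- corner[(k %% 6) + 1, ]
        for (j in seq_len(verts_per_edge) - 1L) {
          p <- centre + a + (j / verts_per_edge) * (b - a)
          key <- key_of(p)
          id <- index[[key]]
          if (is.null(id)) {
            pool <- rbind(pool, p)
            id <- nrow(pool)
            index[[key]] <- id
          }
          loop <- c(loop, id)
        }
      }
      ci <- ci + 1L
      cells[[ci]] <- loop
    }
  }
  dimnames(pool) <- NULL
  tissue_mesh(pool, cells)
}
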