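# Shared fixture builders. Everything is generated in code; no data files.

circle_polygon <- function(radius = 1, n = 360, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  boundary_polygon(cbind(centre[1] + radius * cos(th),
                         centre[2] + radius * sin(th)))
}

unit_square <- function() {
  boundary_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

regular_hexagon <- function(edge = 1) {
  th <- (0:5) * pi / 3
  boundary_polygon(edge * cbind(cos(th), sin(th)))
}

# star-shaped random polygon (valid, CCW) with n vertices
random_star_polygon <- function(n = 20, r_min = 2, r_max = 4) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  boundary_polygon(cbind(r * cos(th), r * sin(th)))
}

# independent shoelace via fan triangulation from the first vertex
fan_triangulation_area <- function(v) {
  v <- unclass(v)
  a <- 0
  for (i in 2:(nrow(v) - 1)) {
    p <- v[i, ] - v[1, ]; q <- v[i + 1, ] - v[1, ]
    a <- a + (p[1] * q[2] - p[2] * q[1]) / 2
  }
  a
}

# numerical gradient of a scalar function of an n x 2 vertex matrix
num_gradient <- function(f, v, h = 1e-6) {
  g <- matrix(0, nrow(v), 2)
  for (i in seq_len(nrow(v))) for (j in 1:2) {
    vp <- v; vm <- v
    vp[i, j] <- vp[i, j] + h
    vm[i, j] <- vm[i, j] - h
    g[i, j] <- (f(vp) - f(vm)) / (2 * h)
  }
  g
}

# count circular TRUE runs (arcs) of length >= min_len
n_circular_arcs <- function(flag, min_len = 1L) {
  n <- length(flag)
  if (!any(flag)) return(0L)
  if (all(flag)) return(1L)
  s <- which(!flag)[1]
  f <- flag[((seq_len(n) + s - 2L) %% n) + 1L]
  r <- rle(f)
  sum(r$values & r$lengths >= min_len)
}

# cache protocol runs shared between acceptance criteria
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(genotype, seed, mode = "combined_factor", ...) {
  key <- paste(genotype, mode, seed, sep = "|")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_protocol(genotype, mode, seed = seed, ...)
  .run_cache[[key]]
}

mean_circ_trace <- function(sim) {
  signal_trace(sim$tissue_summary$mean_circularity,
               diff(sim$tissue_summary$time_min)[1], "mean_circularity")
}
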