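#' Initialize a vertex-model simulation state
#'
#' Builds the hexagonal patch, per-cell phase onsets (the P-to-A wave),
#' D-V stress fibers and all bookkeeping needed by the integrator. The
#' posterior edge of the patch is its maximum-x boundary; ruffling starts
#' there and propagates anteriorly at `params$wave_speed`.
#'
#' @param genotype a genotype name or [genotype()] object.
#' @param mode `"single_factor"` (wild-type oocyte extension for every
#'   genotype) or `"combined_factor"` (genotype-specific extension and the
#'   Rac-inhibition 40-min ruffling override).
#' @param params a [model_params()].
#' @param program a [phase_program()].
#' @param seed integer seed; recorded in the state and every output.
#' @param n_rows,n_cols,edge_len,verts_per_edge patch geometry, see
#'   [hexagonal_tiling()].
#' @return a `sim_state` object.
#' @export
sim_init <- function(genotype = "WT", mode = c("combined_factor", "single_factor"),
                     params = model_params(), program = phase_program(),
                     seed = 1L, n_rows = 3, n_cols = 3, edge_len = 5,
                     verts_per_edge = 4) {
  mode <- match.arg(mode)
  if (is.character(genotype)) genotype <- genotype(genotype)
  stopifnot(inherits(genotype, "genotype"))
  set.seed(seed)

  mesh <- hexagonal_tiling(n_rows, n_cols, edge_len, verts_per_edge)
  ncell <- length(mesh$cells)

  # flattened entry arrays (one entry = one vertex occurrence in one cell)
  ent_v <- ent_prev <- ent_next <- ent_cell <- integer(0)
  for (ci in seq_len(ncell)) {
    loop <- mesh$cells[[ci]]
    L <- length(loop)
    ent_v <- c(ent_v, loop)
    ent_prev <- c(ent_prev, loop[c(L, seq_len(L - 1L))])
    ent_next <- c(ent_next, loop[c(seq_len(L - 1L) + 1L, 1L)])
    ent_cell <- c(ent_cell, rep(ci, L))
  }

  A0 <- vapply(seq_len(ncell), function(ci)
    polygon_measures(mesh_cell_polygon(mesh, ci))$area, numeric(1))
  centroids <- t(vapply(seq_len(ncell), function(ci)
    polygon_measures(mesh_cell_polygon(mesh, ci))$centroid, numeric(2)))
  x_post <- max(mesh$pool[, 1])

  ruff_dur <- program$ruffling_duration
  if (mode == "combined_factor" && !is.na(genotype$ruffling_duration_override))
    ruff_dur <- genotype$ruffling_duration_override

  if (genotype$simultaneous_onset || is.infinite(params$wave_speed)) {
    onsets <- rep(program$wave_t0, ncell)
  } else {
    onsets <- program$wave_t0 + (x_post - centroids[, 1]) / params$wave_speed
  }

  g_eff <- if (mode == "combined_factor") params$g_WT * genotype$g_mult
           else if (genotype$name == "DumpingInhibited") params$g_WT * genotype$g_mult
           else params$g_WT

  fib <- build_dv_fibers(mesh, edge_len)

  state <- structure(list(
    pos = mesh$pool, anc = mesh$anchors, cells = mesh$cells,
    ent_v = ent_v, ent_prev = ent_prev, ent_next = ent_next,
    ent_cell = ent_cell, A0 = A0, onsets = onsets, x_post = x_post,
    fib_a = fib$a, fib_b = fib$b, fib_L0 = fib$L0, fib_cell = fib$cell,
    genotype = genotype, mode = mode, params = params, program = program,
    ruff_dur = ruff_dur, g_eff = g_eff, seed = seed,
    t = 0, last_phase = rep(0L, ncell), rac_cycle = rep(-1L, ncell),
    rac_arc = vector("list", ncell),
    frames = list(), frame_times = numeric(0)
  ), class = "sim_state")
  state <- record_frame(state)
  state
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> %s (%s), t = %g min, %d cells, seed %d\n",
              x$genotype$name, x$mode, x$t, length(x$cells), x$seed))
  invisible(x)
}

# D-V fibers: pair upper-boundary vertices of each cell with the
# nearest-in-x lower-boundary vertex; rest length = initial length.
build_dv_fibers <- function(mesh, edge_len) {
  a <- b <- cell <- integer(0); L0 <- numeric(0)
  for (ci in seq_along(mesh$cells)) {
    loop <- mesh$cells[[ci]]
    v <- mesh$pool[loop, , drop = FALSE]
    cy <- mean(v[, 2]); r <- mean(sqrt((v[, 1] - mean(v[, 1]))^2 + (v[, 2] - cy)^2))
    top <- loop[v[, 2] > cy + 0.35 * r]
    bot <- loop[v[, 2] < cy - 0.35 * r]
    if (!length(top) || !length(bot)) next
    used <- rep(FALSE, length(bot))
    for (tv in top[order(mesh$pool[top, 1])]) {
      dx <- abs(mesh$pool[bot, 1] - mesh$pool[tv, 1])
      dx[used] <- Inf
      j <- which.min(dx)
      if (dx[j] < 0.6 * edge_len) {
        used[j] <- TRUE
        a <- c(a, tv); b <- c(b, bot[j]); cell <- c(cell, ci)
        L0 <- c(L0, sqrt(sum((mesh$pool[tv, ] - mesh$pool[bot[j], ])^2)))
      }
    }
  }
  list(a = a, b = b, L0 = L0, cell = cell)
}

# phase code per cell at time t: 0 pre, 1 ruffling, 2 increasing, 3 spreading
cell_phase <- function(state, t) {
  tau <- t - state$onsets
  p <- state$program
  ifelse(tau < 0, 0L,
    ifelse(tau < state$ruff_dur, 1L,
      ifelse(tau < state$ruff_dur + p$increasing_duration, 2L, 3L)))
}

record_frame <- function(state) {
  state$frames[[length(state$frames) + 1L]] <- state$pos
  state$frame_times <- c(state$frame_times, state$t)
  state
}

#' Advect substrate anchors by oocyte A-P growth
#'
#' Applies one growth increment to the anchors: every anchor's A-P (x)
#' coordinate is scaled about the posterior edge,
#' `x <- x_post + (x - x_post) * (1 + g * dt)`. Vertices are unaffected
#' directly; they follow their anchors only through the adhesion force
#' (the passive-migration pathway). D-V coordinates never change.
#'
#' @param state a `sim_state`.
#' @param g fractional A-P extension per minute (>= 0).
#' @param dt time increment in minutes (default: one integration step).
#' @return the state with updated anchors.
#' @export
apply_oocyte_growth <- function(state, g, dt = state$params$dt) {
  if (g < 0) stop("growth rate g must be >= 0")
  state$anc[, 1] <- state$x_post + (state$anc[, 1] - state$x_post) * (1 + g * dt)
  state
}

# assemble per-entry Rac arrays and per-vertex adhesion coefficients for
# the macro step starting at time t, updating cycle/arc state
schedule_macro <- function(state, t) {
  p <- state$params; prog <- state$program
  gt <- state$genotype
  ncell <- length(state$cells)
  phase <- cell_phase(state, t)

  # fiber rest-length reset at phase transitions (plastic re-engagement)
  changed <- which(phase != state$last_phase)
  if (length(changed) && length(state$fib_a)) {
    sel <- state$fib_cell %in% changed
    if (any(sel)) {
      d <- state$pos[state$fib_b[sel], , drop = FALSE] -
           state$pos[state$fib_a[sel], , drop = FALSE]
      state$fib_L0[sel] <- sqrt(rowSums(d^2))
    }
  }
  state$last_phase <- phase

  ne <- length(state$ent_v)
  rac_amp <- numeric(ne)
  rac_start <- numeric(ne)
  amp_base <- p$f_Rac * gt$rac_mult

  # anterior-facing entries (outward normal pointing anteriorly, -x)
  tx <- state$pos[state$ent_next, 1] - state$pos[state$ent_prev, 1]
  ty <- state$pos[state$ent_next, 2] - state$pos[state$ent_prev, 2]
  tl <- sqrt(tx^2 + ty^2)
  nx <- ifelse(tl > 0, ty / tl, 0)

  release <- rep(1, nrow(state$pos))
  for (ci in seq_len(ncell)) {
    amp <- amp_base * prog$rac_schedule[phase[ci] + 1L]
    if (phase[ci] == 0L || amp <= 0) next
    k <- floor((t - state$onsets[ci]) / p$rac_T)
    cyc_start <- state$onsets[ci] + k * p$rac_T
    ents <- which(state$ent_cell == ci)
    if (phase[ci] == 1L) {
      if (k != state$rac_cycle[ci]) {
        n_arc <- max(3L, round(p$rac_arc_frac * length(ents)))
        s0 <- sample.int(length(ents), 1L)
        state$rac_arc[[ci]] <- ents[((s0 - 1 + seq_len(n_arc) - 1) %% length(ents)) + 1]
        state$rac_cycle[ci] <- k
      }
      act <- state$rac_arc[[ci]]
    } else {
      act <- ents[nx[ents] < -0.3]
      state$rac_cycle[ci] <- k
    }
    if (length(act)) {
      rac_amp[act] <- amp
      rac_start[act] <- cyc_start
      # adhesion release under a fresh Rac pulse (delayed re-engagement)
      if (t - cyc_start < p$adhesion_delay)
        release[state$ent_v[act]] <- p$adhesion_release
    }
  }

  # Rho-gated adhesion coefficient per cell, averaged onto shared vertices
  rho_eff <- p$L_Rho * gt$rho_mult * prog$rho_schedule[phase + 1L]
  gate <- rho_eff^p$hill_n / (p$K_d + rho_eff^p$hill_n)
  coef_cell <- p$f_CAMs * gt$cam_mult * gate
  num <- den <- numeric(nrow(state$pos))
  for (ci in seq_len(ncell)) {
    vs <- state$cells[[ci]]
    num[vs] <- num[vs] + coef_cell[ci]
    den[vs] <- den[vs] + 1
  }
  adh_coef <- ifelse(den > 0, num / den, 0) * release

  fib_k <- p$K_Fiber * gt$fiber_mult *
    prog$fiber_schedule[phase[state$fib_cell] + 1L]

  # plastic target area once the cell has entered the increasing phase
  A0_tau <- ifelse(phase >= 2L, p$tau_A0, 0)

  list(state = state, rac_amp = rac_amp, rac_start = rac_start,
       adh_coef = adh_coef, fib_k = as.numeric(fib_k), A0_tau = A0_tau)
}

#' Advance a simulation
#'
#' Integrates the equation of motion for `minutes` of simulated time in
#' macro-steps of `params$frame_dt`: schedules (Rac pulse targets, Rho and
#' fiber multipliers, adhesion release, anchor turnover) are refreshed at
#' each macro-step boundary, and the inner finite-difference loop runs in
#' compiled code at step `params$dt`. A frame is recorded after every
#' macro-step.
#'
#' @param state a `sim_state` from [sim_init()].
#' @param minutes simulated duration to advance (multiple of `frame_dt`).
#' @return the advanced state.
#' @export
sim_advance <- function(state, minutes) {
  p <- state$params
  n_macro <- round(minutes / p$frame_dt)
  n_sub <- round(p$frame_dt / p$dt)
  for (m in seq_len(n_macro)) {
    t <- state$t
    # anchor turnover: re-seat anchors to current vertex positions
    if (p$anchor_turnover_time > 0 && t > 0 &&
        abs(t / p$anchor_turnover_time - round(t / p$anchor_turnover_time)) < 1e-9)
      state$anc <- state$pos
    sched <- schedule_macro(state, t)
    state <- sched$state
    g_now <- if (t >= state$ruff_dur) state$g_eff else 0
    out <- fw_integrate(state$pos, state$anc,
                        state$ent_v - 1L, state$ent_prev - 1L,
                        state$ent_next - 1L, state$ent_cell - 1L,
                        state$A0, sched$A0_tau, p$K_L, p$K_a,
                        sched$rac_amp, sched$rac_start, p$rac_sigma, p$rac_T,
                        sched$adh_coef,
                        state$fib_a - 1L, state$fib_b - 1L,
                        state$fib_L0, sched$fib_k,
                        p$f_R, p$eta_vis, p$dt, t, n_sub,
                        g_now, state$x_post)
    state$pos <- out$pos
    state$anc <- out$anc
    state$A0 <- out$A0
    state$t <- t + n_sub * p$dt
    state <- record_frame(state)
  }
  state
}

#' Run a full simulation protocol
#'
#' Runs one genotype through the complete phase program (wild type:
#' 60 min ruffling, then 100 min increasing + spreading) and returns the
#' recorded trajectory together with per-cell, per-frame shape measures and
#' tissue-level summaries. In `single_factor` mode all genotypes experience
#' the wild-type oocyte extension so that the perturbed mechanism is the
#' only difference; `combined_factor` mode adds the experimentally observed
#' genotype-specific extension rates (and the 40-min ruffling override for
#' Rac inhibition).
#'
#' @inheritParams sim_init
#' @param total_minutes protocol duration; default = sum of phase durations.
#' @return a `fw_simulation` list: `state`, `cell_summary` (data.frame:
#'   cell_id, time_min, area_um2, perimeter_um, circularity, centroid_x,
#'   centroid_y, ruffle_arcs), `tissue_summary` (data.frame: time_min,
#'   mean_circularity, mean_area_um2, mean_pa_displacement_um,
#'   wave_front_x_um), and `manifest` (genotype, mode, seed, g used, ...).
#' @examples
#' \donttest{
#' sim <- run_protocol("WT", seed = 1, n_rows = 2, n_cols = 2)
#' head(sim$tissue_summary)
#' }
#' @export
run_protocol <- function(genotype = "WT",
                         mode = c("combined_factor", "single_factor"),
                         params = model_params(), program = phase_program(),
                         seed = 1L, n_rows = 3, n_cols = 3, edge_len = 5,
                         verts_per_edge = 4, total_minutes = NULL) {
  mode <- match.arg(mode)
  state <- sim_init(genotype, mode, params, program, seed,
                    n_rows, n_cols, edge_len, verts_per_edge)
  if (is.null(total_minutes))
    total_minutes <- state$ruff_dur + program$increasing_duration +
      program$spreading_duration
  state <- sim_advance(state, total_minutes)
  summarize_simulation(state)
}

# per-cell and tissue summaries from the recorded frames
summarize_simulation <- function(state) {
  ncell <- length(state$cells)
  nfr <- length(state$frames)
  rows <- vector("list", nfr * ncell)
  k <- 0L
  init_cx <- numeric(ncell)
  for (fi in seq_len(nfr)) {
    tmin <- state$frame_times[fi]
    pool <- state$frames[[fi]]
    for (ci in seq_len(ncell)) {
      v <- pool[state$cells[[ci]], , drop = FALSE]
      pm <- polygon_measures(v)
      circ <- 4 * pi * pm$area / pm$perimeter^2
      kap <- discrete_curvature(boundary_polygon(v), smooth_window = 3L)
      n_arcs <- count_arcs(kap > 2 / pm$equivdiameter, min_len = 3L)
      if (fi == 1L) init_cx[ci] <- pm$centroid[1]
      k <- k + 1L
      rows[[k]] <- data.frame(cell_id = ci, time_min = tmin,
                              area_um2 = pm$area, perimeter_um = pm$perimeter,
                              circularity = circ,
                              centroid_x = pm$centroid[1],
                              centroid_y = pm$centroid[2],
                              ruffle_arcs = n_arcs)
    }
  }
  cell_summary <- do.call(rbind, rows)
  tissue <- do.call(rbind, lapply(seq_len(nfr), function(fi) {
    sub <- cell_summary[cell_summary$time_min == state$frame_times[fi], ]
    started <- which(state$onsets <= state$frame_times[fi])
    data.frame(time_min = state$frame_times[fi],
               mean_circularity = mean(sub$circularity),
               mean_area_um2 = mean(sub$area_um2),
               mean_pa_displacement_um = mean(init_cx - sub$centroid_x),
               wave_front_x_um = if (length(started))
                 min(sub$centroid_x[started]) else NA_real_)
  }))
  manifest <- list(package = "folliclewave",
                   version = as.character(utils::packageVersion("folliclewave")),
                   genotype = state$genotype$name, mode = state$mode,
                   seed = state$seed, g_used = state$g_eff,
                   ruffling_duration = state$ruff_dur,
                   n_cells = ncell, n_frames = nfr)
  structure(list(state = state, cell_summary = cell_summary,
                 tissue_summary = tissue, manifest = manifest),
            class = "fw_simulation")
}

#' @export
print.fw_simulation <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<fw_simulation> %s (%s), seed %d, %d cells x %d frames\n",
              m$genotype, m$mode, m$seed, m$n_cells, m$n_frames))
  invisible(x)
}

# contiguous TRUE runs on a circular index set, counted if >= min_len
count_arcs <- function(flag, min_len = 1L) {
  n <- length(flag)
  if (!any(flag)) return(0L)
  if (all(flag)) return(1L)
  # rotate so position 1 is FALSE, then count linear runs
  s <- which(!flag)[1]
  f <- flag[((seq_len(n) + s - 2L) %% n) + 1L]
  r <- rle(f)
  sum(r$values & r$lengths >= min_len)
}
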