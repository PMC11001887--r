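#' Mechanical parameters of the modified vertex model
#'
#' Every vertex of the basal cell outline moves overdamped under six forces:
#' cortical line tension, areal elasticity, Rac1-driven protrusion pulses,
#' Hill-gated focal-adhesion springs to substrate anchors, one-sided D-V
#' stress-fiber springs, and Gaussian noise. The parameter set is
#' dimensionless-calibrated (force units are arbitrary; lengths in um, time
#' in min) because the source model cites literature values without a table;
#' defaults are fixed once so that the wild-type phase sequence emerges and
#' are exposed here and in the config file format.
#'
#' @param eta_vis drag coefficient (force.min/um).
#' @param K_L cortical line tension / spring constant (force/um).
#' @param K_a areal elastic modulus (force/um^3).
#' @param f_Rac integrated strength of one Rac protrusion pulse (force.min).
#' @param rac_sigma standard deviation of the Rac pulse (min).
#' @param rac_T duration of one activated Rac cycle (min).
#' @param rac_arc_frac fraction of the cell boundary recruited by one
#'   ruffling-phase Rac pulse.
#' @param f_CAMs adhesion strength of the cell-adhesion molecules (force/um).
#' @param L_Rho baseline RhoA GTPase concentration (dimensionless).
#' @param K_d apparent Hill dissociation constant of adhesion on Rho.
#' @param hill_n Hill coefficient (>= 1).
#' @param K_Fiber stress-fiber spring constant (force/um).
#' @param tau_A0 relaxation time (min) with which the target area tracks
#'   the attained basal area once a cell enters the increasing phase
#'   (basal flattening redistributes apical volume to the basal plane);
#'   the target is frozen before that.
#' @param f_R noise force strength (force).
#' @param dt integration time step (min); must satisfy
#'   `dt < eta_vis / k_max` with `k_max` the largest effective stiffness
#'   (adhesion + tension + area, about 0.8 here).
#' @param adhesion_delay delay between Rac activation of a membrane segment
#'   and re-engagement of its focal adhesions (min).
#' @param adhesion_release fraction of adhesion strength retained on a
#'   membrane segment during the `adhesion_delay` after Rac activation.
#' @param anchor_turnover_time period on which substrate anchors are
#'   re-seated to the current vertex positions (min).
#' @param g_WT wild-type oocyte A-P extension rate from nurse-cell dumping
#'   (fractional extension per min).
#' @param wave_speed speed of the posterior-to-anterior ruffling-onset wave
#'   (um/min).
#' @param frame_dt interval at which frames are recorded (min).
#' @return a `model_params` list.
#' @export
model_params <- function(eta_vis = 1, K_L = 0.05, K_a = 0.01,
                         f_Rac = 3, rac_sigma = 4, rac_T = 20,
                         rac_arc_frac = 0.25,
                         f_CAMs = 1, L_Rho = 1, K_d = 1, hill_n = 2,
                         K_Fiber = 0.05, tau_A0 = 15, f_R = 0.01, dt = 0.01,
                         adhesion_delay = 3, adhesion_release = 0.5,
                         anchor_turnover_time = 5,
                         g_WT = 0.006, wave_speed = 8, frame_dt = 1) {
  p <- list(eta_vis = eta_vis, K_L = K_L, K_a = K_a, f_Rac = f_Rac,
            rac_sigma = rac_sigma, rac_T = rac_T, rac_arc_frac = rac_arc_frac,
            f_CAMs = f_CAMs, L_Rho = L_Rho, K_d = K_d, hill_n = hill_n,
            K_Fiber = K_Fiber, tau_A0 = tau_A0, f_R = f_R, dt = dt,
            adhesion_delay = adhesion_delay,
            adhesion_release = adhesion_release,
            anchor_turnover_time = anchor_turnover_time,
            g_WT = g_WT, wave_speed = wave_speed, frame_dt = frame_dt)
  with(p, {
    if (any(c(eta_vis, K_L, K_a, dt, rac_sigma, rac_T, K_d) <= 0))
      stop("eta_vis, K_L, K_a, dt, rac_sigma, rac_T, K_d must be positive")
    if (hill_n < 1) stop("hill_n must be >= 1")
    if (adhesion_delay < 0 || f_R < 0 || f_CAMs < 0 || K_Fiber < 0 ||
        g_WT < 0 || tau_A0 < 0)
      stop("negative parameter where a non-negative value is required")
    if (wave_speed <= 0) stop("wave_speed must be positive (Inf = simultaneous onset)")
  })
  class(p) <- "model_params"
  p
}

#' Phase program of the expansion wave
#'
#' The protocol runs three phases per cell, offset by the P-to-A wave:
#' ruffling (random-membrane Rac pulses, Rho low, adhesions weak), area
#' increasing (Rac shifts to the anterior membrane, Rho recovers) and
#' spreading (Rho high, fibers re-engaged, oocyte growth drives passive
#' migration). A cell enters ruffling at
#' `wave_t0 + distance_from_posterior / wave_speed`. Rho and fiber schedules
#' are piecewise-constant multipliers per phase (pre-wave, ruffling,
#' increasing, spreading).
#'
#' @param ruffling_duration,increasing_duration,spreading_duration phase
#'   lengths in minutes; wild-type totals 60 + (20 + 80) = 160 min.
#' @param wave_t0 time at which the wave reaches the posterior edge (min).
#' @param rho_schedule,fiber_schedule,rac_schedule length-4 multipliers
#'   applied to `L_Rho`, `K_Fiber` and `f_Rac` in phases (pre, ruffling,
#'   increasing, spreading). Rho is reduced during ruffling and ramped high
#'   in spreading; Rac pulses run at full strength on random membrane during
#'   ruffling and at reduced strength on the anterior membrane afterwards
#'   (residual protrusions).
#' @return a `phase_program` list.
#' @export
phase_program <- function(ruffling_duration = 60, increasing_duration = 20,
                          spreading_duration = 80, wave_t0 = 0,
                          rho_schedule = c(pre = 1, ruffling = 0.3,
                                           increasing = 1, spreading = 1.5),
                          fiber_schedule = c(pre = 1, ruffling = 1,
                                             increasing = 0.2, spreading = 1),
                          rac_schedule = c(pre = 0, ruffling = 1,
                                           increasing = 0.25, spreading = 0.2)) {
  if (any(c(ruffling_duration, increasing_duration, spreading_duration) < 0))
    stop("phase durations must be >= 0")
  if (length(rho_schedule) != 4L || length(fiber_schedule) != 4L ||
      length(rac_schedule) != 4L)
    stop("schedules must have 4 entries (pre, ruffling, increasing, spreading)")
  structure(list(ruffling_duration = ruffling_duration,
                 increasing_duration = increasing_duration,
                 spreading_duration = spreading_duration,
                 wave_t0 = wave_t0,
                 rho_schedule = rho_schedule,
                 fiber_schedule = fiber_schedule,
                 rac_schedule = rac_schedule),
            class = "phase_program")
}

#' Genotype presets
#'
#' Genetic perturbations enter the model as multipliers on the corresponding
#' force parameters: Rac inhibition scales `f_Rac`, Rho inhibition scales
#' `L_Rho` (and, through reduced actomyosin, the fiber stiffness), focal
#' adhesion perturbations scale `f_CAMs` and `K_Fiber`, and dumping
#' inhibition scales the oocyte A-P growth rate `g`. Weak inhibition is
#' 0.5x, strong 0.1x, overexpression 2x. `g_mult` is only applied in
#' combined-factor mode (single-factor simulations pre-set the wild-type
#' extension for every genotype, except `DumpingInhibited` whose single
#' factor is the extension itself). `DumpingInhibited` also starts ruffling
#' simultaneously across the tissue (infinite wave speed), matching the loss
#' of the P-to-A wave when dumping is blocked.
#'
#' @param name one of `names(genotype_presets())`.
#' @return a `genotype` list with fields `name`, `rac_mult`, `rho_mult`,
#'   `cam_mult`, `fiber_mult`, `g_mult`, `ruffling_duration_override`
#'   (NA = none) and `simultaneous_onset`.
#' @examples
#' genotype("Rac1DN_weak")
#' @export
genotype <- function(name = "WT") {
  presets <- genotype_presets()
  if (!name %in% names(presets))
    stop("unknown genotype '", name, "'; presets: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' @rdname genotype
#' @export
genotype_presets <- function() {
  mk <- function(name, rac = 1, rho = 1, cam = 1, fiber = 1, g = 1,
                 ruff_override = NA_real_, simultaneous = FALSE) {
    structure(list(name = name, rac_mult = rac, rho_mult = rho,
                   cam_mult = cam, fiber_mult = fiber, g_mult = g,
                   ruffling_duration_override = ruff_override,
                   simultaneous_onset = simultaneous),
              class = "genotype")
  }
  list(
    WT               = mk("WT"),
    # Rac inhibition blocks ruffling early: 40 min ruffling in combined mode
    Rac1DN_weak      = mk("Rac1DN_weak",   rac = 0.5, g = 0.5, ruff_override = 40),
    Rac1DN_strong    = mk("Rac1DN_strong", rac = 0.1, g = 0.1, ruff_override = 40),
    Rho1DN           = mk("Rho1DN",  rho = 0.1, fiber = 0.3, g = 0.3),
    PaxOE            = mk("PaxOE",   cam = 2,   fiber = 2,   g = 1.2),
    TalinRNAi        = mk("TalinRNAi", cam = 0.5, fiber = 0.5, g = 0.7),
    DumpingInhibited = mk("DumpingInhibited", g = 0.05, simultaneous = TRUE)
  )
}
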