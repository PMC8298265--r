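# Explicit cosimulation coupling between the 1D pulmonary network and
# the 0D left atrium.  Each step: (i) the atrial inflow is predicted by
# under-relaxation of the vein-outlet flows, (ii) the chamber advances
# and returns its pressure, (iii) that pressure becomes the vein-outlet
# boundary condition of the network for the same step.

#' Relaxed interface-flow update
#'
#' Predictor for the atrial-side inflow:
#' `q_LA(n+1) = q_LA(n) + theta1 (q_PC(n) - q_LA(n))
#'            + theta2 (q_PC(n) - q_PC(n-1))`,
#' applied per vein.  Fixed points are exactly the matched states
#' q_LA = q_PC with q_PC stationary.
#'
#' @param q_la current atrial-side inflow(s).
#' @param q_pc current pulmonary-side outlet flow(s).
#' @param q_pc_prev previous-step pulmonary-side flow(s).
#' @param theta1,theta2 relaxation parameters in `[0, 1]`.
#' @return the predicted next atrial-side inflow(s).
#' @export
coupling_update <- function(q_la, q_pc, q_pc_prev, theta1 = 0.5,
                            theta2 = 0.5) {
  stopifnot(theta1 >= 0, theta1 <= 1, theta2 >= 0, theta2 <= 1)
  q_la + theta1 * (q_pc - q_la) + theta2 * (q_pc - q_pc_prev)
}

#' Pressure handoff to the vein outlets
#'
#' The chamber pressure is broadcast to every pulmonary-vein outlet as
#' its pressure boundary condition for the next step.
#'
#' @param p_la atrial chamber pressure (Pa).
#' @param n_veins number of vein outlets.
#' @return vector of outlet pressures, length `n_veins`.
#' @export
pressure_handoff <- function(p_la, n_veins = 4L) rep(p_la, n_veins)

#' Relaxation-parameter schedule
#'
#' The default pair is used through most of the cycle; the reduced pair
#' takes over while the atrial pressure changes rapidly (mitral-valve
#' closure), detected by a threshold on |dp_LA/dt|.
#'
#' @param default,reduced the two `(theta1, theta2)` pairs.
#' @param trigger_mmHg_s threshold on |dp_LA/dt| in mmHg/s.
#' @return list of class `theta_schedule`.
#' @export
theta_schedule <- function(default = c(0.5, 0.5), reduced = c(0.1, 0.1),
                           trigger_mmHg_s = 200) {
  stopifnot(all(default >= 0 & default <= 1), all(reduced >= 0 & reduced <= 1))
  structure(list(default = default, reduced = reduced,
                 trigger = mmHg_to_Pa(trigger_mmHg_s)),
            class = "theta_schedule")
}

#' Initialise the coupled system
#'
#' Pre-runs the stand-alone pulmonary model (default ten cycles) under
#' the typical atrial pressure waveform, then pre-runs the 0D atrium
#' for 0.1 s with the pre-run's vein outflows as prescribed inflow, so
#' that the interface flows and pressures are matched when coupling
#' starts.
#'
#' @param net a `pulmo_network`.
#' @param case a [case_config()].
#' @param la_pars an [la_surrogate()].
#' @param steps_per_cycle,prerun_cycles,tol,n_harmonics,valve see
#'   [simulate_pulmonary()].
#' @param ... passed to [simulate_pulmonary()].
#' @return list with the pre-run (`prerun`), the primed atrial state
#'   (`la_state`), the matched interface flows (`q_la`) and the warm
#'   network state (`warm`).
#' @export
initialize_coupled <- function(net, case = case_config("control"),
                               la_pars = la_surrogate(),
                               steps_per_cycle = 16384L, prerun_cycles = 10,
                               tol = 1e-3, n_harmonics = 512,
                               valve = valve_params(), ...) {
  prerun <- simulate_pulmonary(net, case, steps_per_cycle = steps_per_cycle,
                               cycles = prerun_cycles, tol = tol,
                               n_harmonics = n_harmonics, valve = valve, ...)
  period <- case$period
  dt <- period / steps_per_cycle
  lv_fn <- lv_pressure_waveform(period = period, systolic = case$lv_systolic,
                                end_diastolic = case$lv_end_diastolic,
                                diastolic_min = case$lv_diastolic_min,
                                systole = case$systole)
  prof <- active_tension_profile(duration = case$activation_duration)
  active_fn <- function(t) active_scaling(t, prof, case)
  la_env <- list(pars = la_pars, lv_fn = lv_fn, active_fn = active_fn,
                 period = period, systole = case$systole, nsub = 1L)
  # chamber pre-run over the last 0.1 s of the cycle, fed by the
  # pre-run vein outflows; volume initialised from the typical pressure
  t0 <- period - 0.1
  p_typ <- la_pressure_waveform(period = period)
  a0 <- active_fn(t0)
  V <- la_pars$V0 + p_typ(t0) / (la_pars$E_pas + a0 * la_pars$E_act)
  state <- list(V = V, p_la = p_typ(t0), q_mv = 0, dpdt = 0)
  i0 <- max(1L, as.integer(round(t0 / dt)))
  for (s in i0:steps_per_cycle) {
    q_in <- sum(prerun$q_outlet[s, ])
    state <- .la_advance(state, q_in, (s - 1L) * dt, dt, la_env)
  }
  q_la <- prerun$q_outlet[steps_per_cycle, ]
  list(prerun = prerun, la_state = state, q_la = q_la,
       la_env = la_env,
       warm = prerun$state)
}

#' Coupled pulmonary-atrial simulation
#'
#' Runs the explicit cosimulation: the pre-run initialisation, then
#' coupled cycles until the cycle-to-cycle change of the midpoint fields
#' falls below `tol`.  Growing interface oscillations abort with a
#' suggestion to reduce the relaxation parameters.
#'
#' @inheritParams initialize_coupled
#' @param cycles maximum number of coupled cycles.
#' @param theta a [theta_schedule()].
#' @param skip_prerun logical; start the coupled run from rest instead
#'   of the matched pre-run state (slower convergence, for robustness
#'   experiments).
#' @param nsub chamber substeps per network time step (the interface
#'   exchange stays at the network step; the chamber integrates on the
#'   finer grid).
#' @param init_from optional result of [initialize_coupled()] to reuse.
#' @return a `pulmo_run` with an `$la` component (chamber volume,
#'   pressure, mitral and relaxed vein flows per step).
#' @export
simulate_coupled <- function(net, case = case_config("control"),
                             la_pars = la_surrogate(),
                             steps_per_cycle = 16384L, cycles = 8,
                             prerun_cycles = 10, tol = 1e-3,
                             n_harmonics = 512, valve = valve_params(),
                             theta = theta_schedule(),
                             skip_prerun = FALSE, nsub = 1L,
                             init_from = NULL, ...) {
  period <- case$period
  dt <- period / steps_per_cycle
  rv <- rv_pressure_waveform(period = period, systolic = case$rv_systolic,
                             systole = case$systole)
  if (case$label == "amr")
    la_pars$mv$A_reg <- case$regurgitant_area_cm2 * 1e-4
  if (skip_prerun) {
    lv_fn <- lv_pressure_waveform(period = period, systolic = case$lv_systolic,
                                  end_diastolic = case$lv_end_diastolic,
                                  diastolic_min = case$lv_diastolic_min,
                                  systole = case$systole)
    prof <- active_tension_profile(duration = case$activation_duration)
    la_env <- list(pars = la_pars, lv_fn = lv_fn,
                   active_fn = function(t) active_scaling(t, prof, case),
                   period = period, systole = case$systole, nsub = 1L)
    p00 <- la_pressure_waveform(period = period)(0)
    state <- list(V = la_pars$V0 + p00 / la_pars$E_pas, p_la = p00,
                  q_mv = 0, dpdt = 0)
    ini <- list(la_state = state, q_la = numeric(length(net$outlets)),
                la_env = la_env, warm = NULL, prerun = NULL)
  } else if (!is.null(init_from)) {
    ini <- init_from
    ini$la_env$pars <- la_pars
  } else {
    ini <- initialize_coupled(net, case, la_pars,
                              steps_per_cycle = steps_per_cycle,
                              prerun_cycles = prerun_cycles, tol = tol,
                              n_harmonics = n_harmonics, valve = valve, ...)
  }
  la <- c(ini$la_env, list(
    state = ini$la_state, q_la = ini$q_la,
    q_pc_prev = ini$q_la,
    theta_default = theta$default, theta_reduced = theta$reduced,
    theta_trigger = theta$trigger))
  la$pars <- la_pars
  la$nsub <- as.integer(nsub)
  bc <- list(inlet = list(type = "valve", p_fn = rv, valve = valve))
  run <- run_to_periodic(net, bc, dt = dt, steps_per_cycle = steps_per_cycle,
                         cycles = cycles, tol = tol,
                         n_harmonics = n_harmonics, la = la,
                         warm = ini$warm,
                         trees = if (!is.null(ini$prerun)) ini$prerun$trees)
  run$case <- case
  run$prerun <- ini$prerun
  run
}
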