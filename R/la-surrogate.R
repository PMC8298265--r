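#' Scenario presets: control, atrial fibrillation, acute mitral
#' regurgitation
#'
#' Returns the boundary-condition anchors and timing for the three
#' study scenarios: the healthy control (T = 0.8 s, RV systolic
#' 26 mmHg, LV 10/110 mmHg end-diastolic/systolic), atrial fibrillation
#' (as control but with the atrial active contraction removed) and
#' acute mitral regurgitation (T = 0.6 s, RV systolic 34 mmHg, LV
#' 20/100 mmHg, regurgitant mitral orifice open during systole).
#' Ventricular systole lasts 0.36 s at T = 0.8 s and scales with the
#' period; the atrial activation window lasts 0.12 s at end diastole.
#'
#' @param label one of `"control"`, `"af"`, `"amr"`.
#' @param regurgitant_area_cm2 effective regurgitant orifice in the AMR
#'   case (cm^2).
#' @return a list of class `case_config`.
#' @export
case_config <- function(label = c("control", "af", "amr"),
                        regurgitant_area_cm2 = 0.35) {
  label <- match.arg(label)
  amr <- label == "amr"
  period <- if (amr) 0.6 else 0.8
  structure(list(
    label = label,
    period = period,
    rv_systolic = if (amr) 34.0 else 26.0,
    lv_end_diastolic = if (amr) 20.0 else 10.0,
    lv_systolic = if (amr) 100.0 else 110.0,
    lv_diastolic_min = if (amr) 8.0 else 4.0,
    systole = 0.36 * period / 0.8,
    active = label != "af",
    activation_duration = 0.12 * period / 0.8,
    activation_offset = 0.04 * period / 0.8,
    regurgitant_area_cm2 = if (amr) regurgitant_area_cm2 else 0,
    dt_reference = period / 16384), class = "case_config")
}

#' Atrial active-tension profile
#'
#' Normalised piecewise-linear activation a(t) of the atrial wall:
#' a symmetric triangle over the activation window at end diastole,
#' peaking at 1 (which scales the peak isometric tension, 33.7 kPa in
#' the reference model; the 0D chamber uses the dimensionless scaling
#' through its active elastance).
#'
#' @param duration activation window length in s.
#' @param peak_kPa peak active tension represented by a = 1 (kPa);
#'   retained for reference and reporting.
#' @return a list of class `active_tension_profile`.
#' @export
active_tension_profile <- function(duration = 0.12, peak_kPa = 33.7) {
  structure(list(duration = duration, peak_kPa = peak_kPa),
            class = "active_tension_profile")
}

#' Normalised atrial activation at a time in the cycle
#'
#' Returns a(t) in `[0, 1]`: zero outside the end-diastolic activation
#' window, a symmetric triangle peaking at 1 inside it, and identically
#' zero in atrial-fibrillation mode (the active stress is removed).
#' The window ends `activation_offset` after the cycle boundary, so the
#' tail of atrial relaxation reaches into early ventricular systole
#' (which is what launches the first systolic venous inflow wave).
#'
#' @param t time in the cycle in s (vectorised); the cycle starts at the
#'   onset of ventricular systole.
#' @param profile an [active_tension_profile()].
#' @param case a [case_config()].
#' @return numeric vector in `[0, 1]`.
#' @export
active_scaling <- function(t, profile = active_tension_profile(),
                           case = case_config("control")) {
  if (!case$active) return(numeric(length(t)) + 0)
  T <- case$period; d <- case$activation_duration
  off <- case$activation_offset %||% 0
  w <- (t - (T - d + off)) %% T  # time since window start
  s <- w / d
  a <- 1 - abs(2 * s - 1)
  a[s > 1] <- 0
  a
}

#' Mitral-valve surrogate parameters
#'
#' Effective-orifice description of the mitral valve for the 0D left
#' atrium: forward flow through `A_fwd` when the atrial pressure
#' exceeds the ventricular pressure, and (in the regurgitant
#' configuration) systolic backflow into the atrium through `A_reg`.
#'
#' @param A_fwd_cm2 effective forward orifice area (cm^2).
#' @param A_reg_cm2 regurgitant orifice area (cm^2); 0 for a competent
#'   valve.
#' @param cd discharge coefficient.
#' @return list of class `mv_surrogate`.
#' @export
mv_surrogate <- function(A_fwd_cm2 = 8, A_reg_cm2 = 0, cd = 0.8) {
  structure(list(A_fwd = A_fwd_cm2 * 1e-4, A_reg = A_reg_cm2 * 1e-4, cd = cd),
            class = "mv_surrogate")
}

#' Mitral orifice flow
#'
#' Orifice (Bernoulli) law: forward flow
#' `q = cd A_fwd sqrt(2 (p_la - p_lv) / rho)` when the gradient is
#' favourable; when the ventricular pressure dominates, flow is zero
#' for a competent valve and negative (regurgitant, into the atrium)
#' through the regurgitant orifice during systole.
#'
#' @param p_la,p_lv atrial and ventricular pressure in Pa.
#' @param valve an [mv_surrogate()].
#' @param systole logical: is the ventricle in systole?
#' @param rho blood density (kg/m^3).
#' @return flow in m^3/s (positive from atrium to ventricle).
#' @export
mv_flow <- function(p_la, p_lv, valve = mv_surrogate(), systole = FALSE,
                    rho = 1e3) {
  dp <- p_la - p_lv
  q <- numeric(length(dp))
  fwd <- dp > 0
  q[fwd] <- valve$cd * valve$A_fwd * sqrt(2 * dp[fwd] / rho)
  if (valve$A_reg > 0) {
    reg <- !fwd & systole
    q[reg] <- -valve$cd * valve$A_reg * sqrt(-2 * dp[reg] / rho)
  }
  q
}

#' Reduced-order left-atrium parameters
#'
#' Two-term elastance surrogate for the atrial chamber:
#' `p_LA = (E_pas + a(t) E_act) (V - V0)`, with the venous inflows
#' filling the chamber and the mitral orifice draining it.  The default
#' elastances and unstressed volume are calibrated so that the coupled
#' control run produces a stroke volume of about 100 mL with a
#' physiological atrial pressure range (scripts/calibrate_la.R in the
#' source repository reproduces the calibration).
#'
#' @param E_pas_mmHg_mL passive elastance (mmHg/mL).
#' @param E_act_mmHg_mL active elastance gain (mmHg/mL).
#' @param V0_mL unstressed volume (mL).
#' @param mv an [mv_surrogate()].
#' @param C_laa_mL_mmHg appendage compliance for the orifice-velocity
#'   proxy (mL/mmHg).
#' @param A_laa_cm2 appendage orifice area (cm^2).
#' @return list of class `la_surrogate` (SI units internally).
#' @export
la_surrogate <- function(E_pas_mmHg_mL = 0.06, E_act_mmHg_mL = 0.05,
                         V0_mL = 20, mv = mv_surrogate(),
                         C_laa_mL_mmHg = 0.4, A_laa_cm2 = 2) {
  to_si <- 133.322 / 1e-6   # mmHg/mL -> Pa/m^3
  structure(list(
    E_pas = E_pas_mmHg_mL * to_si, E_act = E_act_mmHg_mL * to_si,
    V0 = V0_mL * 1e-6, mv = mv,
    C_laa = C_laa_mL_mmHg * 1e-6 / 133.322, A_laa = A_laa_cm2 * 1e-4,
    E_pas_mmHg_mL = E_pas_mmHg_mL, E_act_mmHg_mL = E_act_mmHg_mL,
    V0_mL = V0_mL), class = "la_surrogate")
}

#' One mass-balance step of the 0D atrial chamber
#'
#' Advances the chamber volume by the net inflow and re-evaluates the
#' elastance pressure: `V <- V + dt (sum(q_in) - q_mv)`,
#' `p_LA = (E_pas + a E_act)(V - V0)`.
#'
#' @param state list with `V` (m^3) and `p_la` (Pa).
#' @param q_in venous inflow(s) in m^3/s (summed).
#' @param q_mv mitral outflow in m^3/s.
#' @param dt time step in s.
#' @param pars an [la_surrogate()].
#' @param a activation scaling in `[0, 1]`.
#' @return updated state list.
#' @export
chamber_step <- function(state, q_in, q_mv, dt, pars = la_surrogate(), a = 0) {
  V <- state$V + dt * (sum(q_in) - q_mv)
  if (V <= 0) stop("atrial volume became non-positive")
  p <- (pars$E_pas + a * pars$E_act) * (V - pars$V0)
  list(V = V, p_la = p)
}

# internal stepper used by the coupled engine: substeps the chamber,
# computing the mitral flow from the instantaneous gradient
.la_advance <- function(state, q_in, t, dt, la) {
  nsub <- la$nsub
  dtt <- dt / nsub
  V <- state$V; p <- state$p_la
  p_old <- p; q_mv <- state$q_mv
  for (j in seq_len(nsub)) {
    tj <- t + (j - 1) * dtt
    sysj <- (tj %% la$period) < la$systole
    q_mv <- mv_flow(p, la$lv_fn(tj), la$pars$mv, systole = sysj)
    V <- V + dtt * (q_in - q_mv)
    if (V <= 0) stop("atrial volume became non-positive")
    a <- la$active_fn(tj + dtt)
    p <- (la$pars$E_pas + a * la$pars$E_act) * (V - la$pars$V0)
  }
  list(V = V, p_la = p, q_mv = q_mv, dpdt = (p - p_old) / dt)
}

#' Left-atrial-appendage orifice-velocity proxy
#'
#' Treats the appendage as a small compliance C hanging off the chamber:
#' the orifice velocity is `u = C (dp_LA/dt) / A_orifice`.  A
#' qualitative diagnostic: its cycle maximum shrinks when the atrial
#' pressure excursions shrink (as in atrial fibrillation) and scales
#' linearly with the assumed compliance.
#'
#' @param p_la atrial pressure series over one cycle (Pa, uniform grid).
#' @param dt sample interval in s.
#' @param pars an [la_surrogate()].
#' @return velocity series in m/s (central differences, periodic ends).
#' @export
laa_velocity_proxy <- function(p_la, dt, pars = la_surrogate()) {
  n <- length(p_la)
  dp <- (p_la[c(2:n, 1)] - p_la[c(n, 1:(n - 1))]) / (2 * dt)
  pars$C_laa * dp / pars$A_laa
}
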