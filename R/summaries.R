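#' Volume and pressure summary of one cardiac cycle
#'
#' Integrates the venous inflows and the mitral flow over one period:
#' stroke volume SV is the total blood volume entering the atrium from
#' the four veins per cycle, split into the filling volume (systole) and
#' conduit volume (diastole); the regurgitant volume is the backflow
#' through the mitral orifice.  When pressures are supplied, the
#' transpulmonary pressure gradient and pulmonary vascular resistance
#' are included.
#'
#' @param q_veins matrix (steps x veins) or vector of total venous
#'   inflow, m^3/s, uniformly sampled over exactly one period.
#' @param period cycle length in s.
#' @param systole ventricular systole duration in s.
#' @param q_mv optional mitral flow series (m^3/s, positive forward).
#' @param p_mpa optional main-pulmonary-artery pressure series (Pa).
#' @param p_la optional atrial pressure series (Pa).
#' @return object of class `cardiac_summary`: list with `SV_mL`,
#'   `V_filling_mL`, `V_conduit_mL`, `V_reg_mL`, `CO_L_min`, and (when
#'   pressures are given) `mPAP_mmHg`, `mLAP_mmHg`, `TPG_mmHg`,
#'   `PVR_mmHg_min_L`.
#' @export
cardiac_params <- function(q_veins, period, systole = 0.36 * period / 0.8,
                           q_mv = NULL, p_mpa = NULL, p_la = NULL) {
  qt <- if (is.matrix(q_veins)) rowSums(q_veins) else q_veins
  n <- length(qt)
  if (!is.null(q_mv) && length(q_mv) != n)
    stop("mitral flow series does not match the venous period")
  dt <- period / n
  t <- (seq_len(n) - 1L) * dt
  sys <- t < systole
  SV <- sum(qt) * dt * 1e6
  Vf <- sum(qt[sys]) * dt * 1e6
  Vc <- sum(qt[!sys]) * dt * 1e6
  Vr <- if (is.null(q_mv)) NA_real_ else -sum(pmin(q_mv, 0)) * dt * 1e6
  out <- list(SV_mL = SV, V_filling_mL = Vf, V_conduit_mL = Vc,
              V_reg_mL = Vr, CO_L_min = SV / 1000 / (period / 60),
              period = period, systole = systole)
  if (!is.null(p_mpa) && !is.null(p_la)) {
    out$mPAP_mmHg <- Pa_to_mmHg(mean(p_mpa))
    out$mLAP_mmHg <- Pa_to_mmHg(mean(p_la))
    tp <- tpg_pvr(out$mPAP_mmHg, out$mLAP_mmHg, out$CO_L_min)
    out$TPG_mmHg <- tp$TPG_mmHg
    out$PVR_mmHg_min_L <- tp$PVR_mmHg_min_L
  }
  structure(out, class = "cardiac_summary")
}

#' @export
print.cardiac_summary <- function(x, ...) {
  cat(sprintf("SV %.1f mL = filling %.1f + conduit %.1f mL; CO %.2f L/min\n",
              x$SV_mL, x$V_filling_mL, x$V_conduit_mL, x$CO_L_min))
  if (!is.na(x$V_reg_mL))
    cat(sprintf("mitral regurgitant volume %.1f mL\n", x$V_reg_mL))
  if (!is.null(x$TPG_mmHg))
    cat(sprintf("mPAP %.1f, mLAP %.1f, TPG %.1f mmHg, PVR %.2f mmHg min/L\n",
                x$mPAP_mmHg, x$mLAP_mmHg, x$TPG_mmHg, x$PVR_mmHg_min_L))
  invisible(x)
}

#' Transpulmonary pressure gradient and pulmonary vascular resistance
#'
#' TPG = mean pulmonary-artery pressure minus mean atrial pressure;
#' PVR = TPG / cardiac output.
#'
#' @param mpap_mmHg mean pulmonary artery pressure (mmHg).
#' @param mlap_mmHg mean left-atrial pressure (mmHg).
#' @param co_L_min cardiac output (L/min), must be positive.
#' @return list with `TPG_mmHg` and `PVR_mmHg_min_L`.
#' @examples
#' tpg_pvr(18.5, 5.3, 7.5)
#' @export
tpg_pvr <- function(mpap_mmHg, mlap_mmHg, co_L_min) {
  if (!is.numeric(co_L_min) || co_L_min <= 0)
    stop("cardiac output must be positive")
  TPG <- mpap_mmHg - mlap_mmHg
  list(TPG_mmHg = TPG, PVR_mmHg_min_L = TPG / co_L_min)
}

#' Summarise a run into cardiac parameters
#'
#' Convenience wrapper building a [cardiac_params()] summary from a
#' `pulmo_run`: venous inflows from the vein outlets, the mitral flow
#' and atrial pressure from the coupled chamber when present (the
#' prescribed outlet pressure otherwise), and the MPA midpoint pressure.
#'
#' @param run a `pulmo_run`.
#' @return a `cardiac_summary`.
#' @export
summarize_run <- function(run) {
  im <- match("MPA", run$vessels)
  sys <- if (!is.null(run$case)) run$case$systole else 0.36 * run$period / 0.8
  p_la <- if (!is.null(run$la)) run$la$p_la else run$p_outlet[, 1]
  cardiac_params(run$q_outlet, period = run$period, systole = sys,
                 q_mv = if (!is.null(run$la)) run$la$q_mv,
                 p_mpa = if (!is.na(im)) run$probe_p[, im],
                 p_la = p_la)
}
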