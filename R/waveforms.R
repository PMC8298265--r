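# Parameterised pressure boundary waveforms.  Shapes are composites of
# half-raised-cosine segments (zero slope at every joint, so the curves
# are periodic and continuously differentiable); the defining scalar
# anchors (systolic peaks, end-diastolic values, 'a'/'v' wave peaks) are
# attained exactly.  All waveform closures take time in seconds and
# return pressure in Pa; timings scale linearly with the period from
# their reference values at T = 0.8 s.

# half-cosine ramp v0 -> v1 over [0, 1]
.hcos <- function(s) (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2
# raised-cosine bump, 0 at the ends of [0, 1], 1 at the centre
.bump <- function(s) ifelse(s > 0 & s < 1, (1 - cos(2 * pi * s)) / 2, 0)

#' Right-ventricular pressure waveform
#'
#' Rounded-trapezoid systolic pulse (half-cosine upstroke, systolic
#' plateau at the anchor pressure, half-cosine downstroke) on a flat
#' diastolic baseline, mimicking the broad right-ventricular ejection
#' pressure.  The systolic maximum is attained exactly; the lumped
#' pulmonary valve upstream of the main pulmonary artery sees this
#' pressure.
#'
#' @param period cardiac period T in s.
#' @param systolic systolic peak pressure in mmHg.
#' @param diastolic diastolic baseline pressure in mmHg.
#' @param systole ventricular systole duration in s (default scales the
#'   0.36 s reference linearly with T / 0.8).
#' @param rise_frac fraction of systole taken by the upstroke.
#' @param fall_frac fraction of systole taken by the downstroke.
#' @return function of time (s) returning pressure in Pa, T-periodic.
#' @export
rv_pressure_waveform <- function(period = 0.8, systolic = 26,
                                 diastolic = 4,
                                 systole = 0.36 * period / 0.8,
                                 rise_frac = 0.25, fall_frac = 0.3) {
  p_d <- mmHg_to_Pa(diastolic); p_s <- mmHg_to_Pa(systolic)
  t1 <- rise_frac * systole; t2 <- (1 - fall_frac) * systole
  function(t) {
    t <- t %% period
    p <- rep(p_d, length(t))
    up <- t < t1
    fl <- t >= t1 & t < t2
    dn <- t >= t2 & t < systole
    p[up] <- p_d + (p_s - p_d) * .hcos(t[up] / t1)
    p[fl] <- p_s
    p[dn] <- p_d + (p_s - p_d) * .hcos((systole - t[dn]) / (systole - t2))
    p
  }
}

#' Left-ventricular pressure waveform
#'
#' Systolic pulse from the end-diastolic value to the systolic peak,
#' isovolumic relaxation to a diastolic minimum, a low-pressure filling
#' plateau, then a late-diastolic rise (the atrial kick) to the
#' end-diastolic pressure, attained exactly at the end of the cycle.
#'
#' @inheritParams rv_pressure_waveform
#' @param systolic systolic peak in mmHg.
#' @param end_diastolic end-diastolic pressure in mmHg (value at t = T).
#' @param diastolic_min early/mid-diastolic minimum in mmHg.
#' @param peak_frac position of the systolic peak within systole.
#' @param relax_dur duration of the post-systolic pressure fall in s.
#' @param edp_rise duration of the late-diastolic rise to the
#'   end-diastolic pressure in s.
#' @return function of time (s) returning pressure in Pa, T-periodic.
#' @export
lv_pressure_waveform <- function(period = 0.8, systolic = 110,
                                 end_diastolic = 10, diastolic_min = 5,
                                 systole = 0.36 * period / 0.8,
                                 peak_frac = 0.45,
                                 relax_dur = 0.1 * period / 0.8,
                                 edp_rise = 0.14 * period / 0.8) {
  p_s <- mmHg_to_Pa(systolic); p_ed <- mmHg_to_Pa(end_diastolic)
  p_min <- mmHg_to_Pa(diastolic_min)
  tp <- peak_frac * systole
  t_rel <- systole + relax_dur   # end of the post-systolic pressure fall
  t_ed <- period - edp_rise      # onset of the late-diastolic rise
  function(t) {
    t <- t %% period
    p <- numeric(length(t))
    i1 <- t < tp
    i2 <- !i1 & t < t_rel
    i3 <- t >= t_rel & t < t_ed
    i4 <- t >= t_ed
    p[i1] <- p_ed + (p_s - p_ed) * .hcos(t[i1] / tp)
    p[i2] <- p_min + (p_s - p_min) * .hcos((t_rel - t[i2]) / (t_rel - tp))
    p[i3] <- p_min
    p[i4] <- p_min + (p_ed - p_min) * .hcos((t[i4] - t_ed) / (period - t_ed))
    p
  }
}

#' Typical left-atrial pressure waveform
#'
#' Smooth T-periodic waveform with an end-systolic 'v' wave and an
#' end-diastolic 'a' wave superposed on a flat baseline; both peaks are
#' attained exactly.  Used as the vein-outlet boundary condition for
#' stand-alone pulmonary simulations and for the coupled pre-run.
#'
#' @inheritParams rv_pressure_waveform
#' @param a_peak end-diastolic 'a' wave peak in mmHg.
#' @param v_peak end-systolic 'v' wave peak in mmHg.
#' @param baseline baseline pressure in mmHg.
#' @return function of time (s) returning pressure in Pa, T-periodic.
#' @export
la_pressure_waveform <- function(period = 0.8, a_peak = 6, v_peak = 9,
                                 baseline = 5) {
  pb <- mmHg_to_Pa(baseline)
  pa <- mmHg_to_Pa(a_peak); pv <- mmHg_to_Pa(v_peak)
  sc <- period / 0.8
  v0 <- 0.20 * sc; v1 <- 0.52 * sc     # 'v' window around end systole
  a0 <- 0.66 * sc; a1 <- 0.80 * sc     # 'a' window at end diastole
  function(t) {
    t <- t %% period
    pb + (pv - pb) * .bump((t - v0) / (v1 - v0)) +
      (pa - pb) * .bump((t - a0) / (a1 - a0))
  }
}

#' @rdname la_pressure_waveform
#' @param t time in s.
#' @return `prescribed_la_pressure` evaluates the default typical
#'   waveform at `t` (Pa).
#' @export
prescribed_la_pressure <- function(t, period = 0.8) {
  la_pressure_waveform(period)(t)
}

#' Build a waveform closure from a declarative spec
#'
#' @param spec list with `kind` ("rv", "lv" or "la") and the named
#'   parameters of the corresponding constructor.
#' @return function of time returning pressure in Pa.
#' @export
make_waveform <- function(spec) {
  kind <- match.arg(spec$kind, c("rv", "lv", "la"))
  spec$kind <- NULL
  fn <- switch(kind, rv = rv_pressure_waveform, lv = lv_pressure_waveform,
               la = la_pressure_waveform)
  do.call(fn, spec)
}
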