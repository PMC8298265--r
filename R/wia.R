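# Wave-intensity analysis: characteristic decomposition of pressure and
# velocity increments into forward ('+', travelling with the mean flow,
# i.e. from the pulmonary vasculature towards the atrium in the veins)
# and backward ('-') components,
#   dp+- = (dp +- rho c du) / 2,   du+- = (du +- dp / (rho c)) / 2,
# with the local pulse wave velocity c from the tube law, and the wave
# intensities W+- = (dp+-/dt)(du+-/dt).

#' Extract a single-probe series from a run
#'
#' Collects one cycle of pressure, flow, area and velocity at the
#' midpoint of a vessel, together with the local wall law, in the form
#' used by the wave-intensity tools.
#'
#' @param run a `pulmo_run`.
#' @param vessel vessel name (e.g. `"LIPV"`).
#' @return an object of class `probe_series` with fields `time`, `p`
#'   (Pa), `q` (m^3/s), `A` (m^2), `u` (m/s), `law`, `fluid`, `period`.
#' @export
probe_series <- function(run, vessel = "MPA") {
  iv <- match(vessel, run$vessels)
  if (is.na(iv)) stop("unknown vessel: ", vessel)
  net <- run$net
  midx <- net$midpoints[iv]
  law <- list(A0 = net$A0[midx], f = net$f[midx], p0 = net$p0,
              EhR0 = net$f[midx] * 3 / 4, R0 = net$R0[midx])
  class(law) <- "wall_law"
  structure(list(
    time = run$time, p = run$probe_p[, iv], q = run$probe_q[, iv],
    A = run$probe_A[, iv], u = run$probe_q[, iv] / run$probe_A[, iv],
    law = law, fluid = net$fluid, period = run$period, vessel = vessel),
    class = "probe_series")
}

# circular central difference on a uniform periodic grid
.cdiff <- function(x) {
  n <- length(x)
  (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / 2
}

#' Characteristic wave decomposition of a probe series
#'
#' @param series a [probe_series()] (uniform grid over one period), or
#'   any list with `time`, `p`, `u`, `A`, `law`, `fluid`.
#' @param c_mode `"pointwise"` evaluates the pulse wave velocity at the
#'   instantaneous area; `"mean"` uses one cycle-mean value.
#' @return an object of class `wia_result`: per-step increments
#'   `dp`, `du`, `dp_fwd`, `dp_bwd`, `du_fwd`, `du_bwd`, intensities
#'   `wi_fwd`, `wi_bwd` (W m^-2 s^-2), the `c` used, and `time`.
#' @export
wia_decompose <- function(series, c_mode = c("pointwise", "mean")) {
  c_mode <- match.arg(c_mode)
  t <- series$time
  n <- length(t)
  if (n < 3) stop("series too short")
  dtv <- diff(t)
  if (max(abs(dtv - dtv[1])) > 1e-9 * dtv[1]) stop("non-uniform time grid")
  dt <- dtv[1]
  rho <- series$fluid$rho
  cc <- wave_speed(series$A, series$law, series$fluid)
  if (c_mode == "mean") cc <- rep(mean(cc), n)
  dp <- .cdiff(series$p); du <- .cdiff(series$u)
  dp_f <- (dp + rho * cc * du) / 2
  dp_b <- (dp - rho * cc * du) / 2
  du_f <- (du + dp / (rho * cc)) / 2
  du_b <- (du - dp / (rho * cc)) / 2
  # The raw backward product (dp-/dt)(du-/dt) = -(dp-/dt)^2/(rho c) is
  # negative semi-definite because du- = -dp-/(rho c); the backward
  # intensity is reported as its positive magnitude, matching the usual
  # practice of plotting forward and backward intensities side by side.
  structure(list(time = t, dt = dt, c = cc, dp = dp, du = du,
                 dp_fwd = dp_f, dp_bwd = dp_b, du_fwd = du_f, du_bwd = du_b,
                 wi_fwd = (dp_f / dt) * (du_f / dt),
                 wi_bwd = -(dp_b / dt) * (du_b / dt),
                 vessel = series$vessel %||% NA_character_),
            class = "wia_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify wave episodes
#'
#' Labels each step of a decomposition by travel direction and
#' compression character (FCW/FDW/BCW/BDW: forward/backward
#' compression/decompression waves, compression meaning dp+- > 0), and
#' merges contiguous same-label steps into episodes with their peak
#' intensity and timing.
#'
#' @param result a [wia_decompose()] result.
#' @param min_peak_frac episodes whose peak intensity falls below this
#'   fraction of the overall maximum intensity are dropped (0 keeps
#'   everything).
#' @return data.frame with columns `label`, `side`, `t_start`, `t_end`,
#'   `t_peak`, `peak_wi`.
#' @export
wia_classify <- function(result, min_peak_frac = 0.01) {
  stopifnot(inherits(result, "wia_result"))
  episodes <- function(dp_side, wi, side) {
    lab <- ifelse(dp_side > 0,
                  if (side == "forward") "FCW" else "BCW",
                  if (side == "forward") "FDW" else "BDW")
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    data.frame(
      label = r$values, side = side,
      t_start = result$time[starts], t_end = result$time[ends],
      t_peak = vapply(seq_along(starts), function(i) {
        w <- starts[i]:ends[i]; result$time[w[which.max(wi[w])]]
      }, numeric(1)),
      peak_wi = vapply(seq_along(starts), function(i)
        max(wi[starts[i]:ends[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  out <- rbind(episodes(result$dp_fwd, result$wi_fwd, "forward"),
               episodes(result$dp_bwd, result$wi_bwd, "backward"))
  wmax <- max(out$peak_wi)
  out <- out[out$peak_wi >= min_peak_frac * wmax, , drop = FALSE]
  out[order(out$t_start), ]
}

#' Pulse wave velocity from the cycle-mean pressure
#'
#' Maps the cycle-mean pressure to an area through the inverse tube law
#' and evaluates the pulse wave velocity there; optionally the
#' cycle-mean of the instantaneous wave speed instead (the two
#' conventions differ slightly because c is nonlinear in p).
#'
#' @param series a [probe_series()].
#' @param mode `"mean_pressure"` (default) or `"mean_c"`.
#' @return wave speed in m/s.
#' @export
pwv_mean_pressure <- function(series, mode = c("mean_pressure", "mean_c")) {
  mode <- match.arg(mode)
  if (mode == "mean_c")
    return(mean(wave_speed(series$A, series$law, series$fluid)))
  A <- tube_law_area(mean(series$p), series$law)
  wave_speed(A, series$law, series$fluid)
}

#' Interior local maxima with a prominence floor
#'
#' @param x numeric series (one cycle).
#' @param prom_frac minimum prominence as a fraction of the series range.
#' @return integer indices of retained peaks.
#' @keywords internal
.find_peaks <- function(x, prom_frac = 0.05) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer())
  rng <- diff(range(x))
  if (rng <= 0) return(integer())
  keep <- vapply(cand, function(i) {
    # prominence: height above the higher of the two surrounding minima
    lo <- if (i > 1) min(x[1:(i - 1)]) else x[i]
    hi <- if (i < n) min(x[(i + 1):n]) else x[i]
    (x[i] - max(lo, hi)) / rng >= prom_frac
  }, logical(1))
  cand[keep]
}

#' Pulmonary-venous flow wave features
#'
#' Detects the four venous flow waves within their phase windows (set
#' by the configured systole duration, not inferred from the signal):
#' the two systolic waves S1 and S2, the early-diastolic D wave and the
#' end-diastolic atrial-reversal AR wave (a negative-flow dip).
#'
#' @param q vein flow over one cycle (m^3/s, uniform grid).
#' @param period cycle length in s.
#' @param systole ventricular systole duration in s.
#' @param prom_frac prominence threshold as a fraction of the flow
#'   range for peak detection.
#' @return data.frame with rows S1, S2, D, AR: `present`, `peak_mL_s`,
#'   `t_peak`.  The AR wave is detected as a prominent late-diastolic
#'   dip (a local minimum caused by the atrial kick); its `peak_mL_s`
#'   is the flow at the dip, negative when the flow actually reverses.
#' @export
venous_wave_features <- function(q, period, systole = 0.36 * period / 0.8,
                                 prom_frac = 0.05) {
  n <- length(q)
  t <- (seq_len(n) - 1L) / n * period
  sc <- period / 0.8
  sys_hi <- systole + 0.08 * sc          # allow the S2 crest to spill over
  pk <- .find_peaks(q, prom_frac)
  pk_sys <- pk[t[pk] < sys_hi]
  s1 <- s2 <- NA_integer_
  if (length(pk_sys) >= 2) {
    s1 <- pk_sys[1]; s2 <- pk_sys[length(pk_sys)]
  } else if (length(pk_sys) == 1) {
    if (t[pk_sys] < 0.5 * systole) s1 <- pk_sys else s2 <- pk_sys
  }
  pk_dia <- pk[t[pk] >= sys_hi & t[pk] < period - 0.10 * sc]
  d <- if (length(pk_dia)) pk_dia[which.max(q[pk_dia])] else NA_integer_
  # AR: prominent local minimum in the last part of diastole
  dip <- .find_peaks(-q, prom_frac)
  dip <- dip[t[dip] >= period - 0.16 * sc]
  ar_i <- if (length(dip)) dip[which.min(q[dip])] else NA_integer_
  ar_present <- !is.na(ar_i)
  row <- function(i, present = !is.na(i)) {
    if (is.na(i)) data.frame(present = present, peak_mL_s = NA_real_,
                             t_peak = NA_real_)
    else data.frame(present = present, peak_mL_s = q[i] * 1e6, t_peak = t[i])
  }
  out <- rbind(S1 = row(s1), S2 = row(s2), D = row(d),
               AR = row(ar_i, ar_present))
  out$wave <- rownames(out)
  out[, c("wave", "present", "peak_mL_s", "t_peak")]
}
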