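#' Write a run to a results directory
#'
#' Emits the probe time series as CSV (columns `time_s`, `vessel`,
#' `x_cm`, `p_mmHg`, `q_mL_s`, `A_cm2`, one block per vessel midpoint),
#' a JSON cardiac summary, an exact echo of the configuration, and a
#' manifest with MD5 checksums of every written file.
#'
#' @param run a `pulmo_run`.
#' @param dir output directory (created if needed).
#' @param config optional [run_config()] to echo.
#' @return invisibly, the manifest as a data.frame.
#' @export
write_run <- function(run, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  net <- run$net
  nv <- length(run$vessels)
  x_cm <- vapply(seq_len(nv), function(v) {
    i <- net$midpoints[v] - net$vessels$i0[v]
    i * m_to_cm(net$vessels$dx_m[v])
  }, numeric(1))
  probes <- do.call(rbind, lapply(seq_len(nv), function(v) {
    data.frame(time_s = run$time, vessel = run$vessels[v], x_cm = x_cm[v],
               p_mmHg = Pa_to_mmHg(run$probe_p[, v]),
               q_mL_s = run$probe_q[, v] * 1e6,
               A_cm2 = run$probe_A[, v] * 1e4)
  }))
  f_probe <- file.path(dir, "probes.csv")
  utils::write.csv(probes, f_probe, row.names = FALSE, quote = FALSE)
  summ <- summarize_run(run)
  f_sum <- file.path(dir, "summary.json")
  jsonlite::write_json(unclass(summ), f_sum, auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(f_probe, f_sum)
  if (!is.null(run$la)) {
    f_la <- file.path(dir, "la.csv")
    utils::write.csv(data.frame(
      time_s = run$time, V_mL = run$la$V * 1e6,
      p_LA_mmHg = Pa_to_mmHg(run$la$p_la),
      q_MV_mL_s = run$la$q_mv * 1e6), f_la, row.names = FALSE, quote = FALSE)
    files <- c(files, f_la)
  }
  if (!is.null(config)) {
    f_cfg <- file.path(dir, "config.json")
    write_config(config, f_cfg)
    files <- c(files, f_cfg)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Plot a run
#'
#' Four diagnostic panels: arterial midpoint pressures, venous midpoint
#' pressures, the inlet (valve) flow, and the venous flows; for coupled
#' runs the atrial pressure joins the venous-pressure panel.
#'
#' @param x a `pulmo_run`.
#' @param ... ignored.
#' @return invisibly `x`.
#' @export
plot.pulmo_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  arts <- which(x$net$vessels$type == "artery")
  veins <- which(x$net$vessels$type == "vein")
  t <- x$time
  graphics::matplot(t, Pa_to_mmHg(x$probe_p[, arts]), type = "l", lty = 1,
                    xlab = "t (s)", ylab = "p (mmHg)", main = "arteries")
  graphics::legend("topright", legend = x$vessels[arts], lty = 1,
                   col = seq_along(arts), cex = 0.6, bty = "n")
  graphics::matplot(t, Pa_to_mmHg(x$probe_p[, veins]), type = "l", lty = 1,
                    xlab = "t (s)", ylab = "p (mmHg)", main = "veins")
  if (!is.null(x$la))
    graphics::lines(t, Pa_to_mmHg(x$la$p_la), lwd = 2)
  graphics::plot(t, x$q_inlet * 1e6, type = "l", xlab = "t (s)",
                 ylab = "q (mL/s)", main = "valve inflow")
  graphics::matplot(t, x$q_outlet * 1e6, type = "l", lty = 1,
                    xlab = "t (s)", ylab = "q (mL/s)", main = "vein outflow")
  invisible(x)
}
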