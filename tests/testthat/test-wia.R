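fl <- fluid_properties()
law <- wall_law(150, R0 = 0.008)

# synthetic probe series helper
mk_series <- function(p, u, period = 0.8, law0 = law) {
  n <- length(p)
  A <- tube_law_area(p, law0)
  list(time = (0:(n - 1)) / n * period, p = p, q = u * A, A = A, u = u,
       law = law0, fluid = fl, period = period, vessel = "SYN")
}

test_that("decomposition identities hold exactly for arbitrary series", {
  set.seed(7)
  n <- 256
  p <- mmHg_to_Pa(12 + 3 * sin(2 * pi * (0:(n - 1)) / n) + rnorm(n, 0, 0.3))
  u <- 0.3 * sin(4 * pi * (0:(n - 1)) / n) + rnorm(n, 0, 0.02)
  res <- wia_decompose(mk_series(p, u))
  expect_equal(res$dp_fwd + res$dp_bwd, res$dp, tolerance = 1e-12)
  expect_equal(res$du_fwd + res$du_bwd, res$du, tolerance = 1e-12)
  # same-direction intensities are non-negative (the backward one is
  # reported as a positive magnitude)
  expect_equal(res$wi_fwd, (res$dp_fwd / res$dt) * (res$du_fwd / res$dt))
  expect_equal(res$wi_bwd, -(res$dp_bwd / res$dt) * (res$du_bwd / res$dt))
  expect_true(all(res$wi_fwd >= 0)); expect_true(all(res$wi_bwd >= 0))
})

test_that("a pure forward wave has no backward component", {
  n <- 512
  ph <- 2 * pi * (0:(n - 1)) / n
  # build du = dp/(rho c) incrementally at the local c
  p <- numeric(n); u <- numeric(n)
  p[1] <- mmHg_to_Pa(10)
  for (i in 2:n) {
    ci <- wave_speed(tube_law_area(p[i - 1], law), law, fl)
    dpi <- mmHg_to_Pa(0.02 * sin(ph[i]))
    p[i] <- p[i - 1] + dpi
    u[i] <- u[i - 1] + dpi / (fl$rho * ci)
  }
  res <- wia_decompose(mk_series(p, u))
  expect_lt(max(abs(res$dp_bwd)) / max(abs(res$dp_fwd)), 2e-3)
  expect_lt(max(res$wi_bwd) / max(res$wi_fwd), 1e-5)
})

test_that("single-step substitution: dp = 2 mmHg with du = 0 splits evenly", {
  rho <- fl$rho
  cc <- 4.0
  dp <- mmHg_to_Pa(2); du <- 0
  dp_f <- (dp + rho * cc * du) / 2
  dp_b <- (dp - rho * cc * du) / 2
  du_f <- (du + dp / (rho * cc)) / 2
  du_b <- (du - dp / (rho * cc)) / 2
  expect_equal(Pa_to_mmHg(dp_f), 1); expect_equal(Pa_to_mmHg(dp_b), 1)
  expect_equal(du_f, dp / (2 * rho * cc))
  expect_equal(du_b, -dp / (2 * rho * cc))
})

test_that("classification labels and episode merging follow the sign runs", {
  n <- 64
  # forward compression vs decompression by construction
  p <- mmHg_to_Pa(10 + cumsum(rep(c(0.1, -0.1), each = n / 2)))
  A <- tube_law_area(p, law)
  cc <- wave_speed(A, law, fl)
  u <- cumsum(c(0, diff(p)) / (fl$rho * mean(cc)))
  res <- wia_decompose(mk_series(p, u))
  cls <- wia_classify(res, min_peak_frac = 0)
  fwd <- cls[cls$side == "forward", ]
  expect_true(all(c("FCW", "FDW") %in% fwd$label))
  # forward-dominant series: FCW episodes while dp rises
  expect_equal(fwd$label[1], "FCW")
  # alternating-sign dp+ gives (sign changes + 1) episodes
  sgn <- sign(res$dp_fwd)
  nchanges <- sum(diff(sgn[sgn != 0]) != 0)
  expect_equal(nrow(fwd), nchanges + 1)
  # per-step label counts are invariant under a circular time shift
  sh <- c(17:n, 1:16)
  res_sh <- wia_decompose(mk_series(p[sh], u[sh]))
  lab <- function(r) table(ifelse(r$dp_fwd > 0, "FCW", "FDW"))
  expect_equal(lab(res_sh), lab(res))
  # and under rescaling p, u (and hence c-consistent q) by one factor
  res_sc <- wia_decompose(mk_series(p, 2 * u))
  expect_equal(sign(res_sc$du), sign(res$du))
})

test_that("pulse wave velocity from mean pressure matches the closed form", {
  n <- 128
  p <- rep(law$p0, n)
  s <- mk_series(p, rep(0, n))
  expect_equal(pwv_mean_pressure(s), sqrt(2 * mmHg_to_Pa(150) / 3000),
               tolerance = 1e-12)
  # mean pressure 26.8 mmHg -> 3.89 m/s (see also the tube-law tests)
  s2 <- mk_series(rep(mmHg_to_Pa(26.8), n), rep(0, n))
  expect_equal(pwv_mean_pressure(s2), 3.89, tolerance = 2e-3)
  # monotone in mean pressure
  s3 <- mk_series(rep(mmHg_to_Pa(30), n), rep(0, n))
  expect_gt(pwv_mean_pressure(s3), pwv_mean_pressure(s2))
  # the two averaging conventions agree for a constant series
  expect_equal(pwv_mean_pressure(s2, "mean_c"), pwv_mean_pressure(s2),
               tolerance = 1e-12)
})

test_that("cardiac volume accounting matches closed-form integrals", {
  period <- 0.8; systole <- 0.36
  n <- 800
  t <- (0:(n - 1)) / n * period
  # constant total inflow: SV = Q T, split by phase durations
  qv <- matrix(25e-6, n, 4)
  cs <- cardiac_params(qv, period, systole)
  expect_equal(cs$SV_mL, 100 * 0.8, tolerance = 1e-9)
  expect_equal(cs$V_filling_mL, 100 * 0.36, tolerance = 1e-9)
  expect_equal(cs$V_conduit_mL, 100 * 0.44, tolerance = 1e-9)
  expect_equal(cs$CO_L_min, 100 * 60 / 1000, tolerance = 1e-9)
  # sinusoidal mitral flow: regurgitant volume is the negative lobe
  qmv <- 1e-4 * sin(2 * pi * t / period)
  cs2 <- cardiac_params(qv, period, systole, q_mv = qmv)
  expect_equal(cs2$V_reg_mL, 1e-4 * period / pi * 1e6, tolerance = 1e-3)
  # non-negative mitral flow: zero regurgitation
  cs3 <- cardiac_params(qv, period, systole, q_mv = pmax(qmv, 0))
  expect_equal(cs3$V_reg_mL, 0)
  expect_error(cardiac_params(qv, period, systole, q_mv = qmv[1:10]),
               "match")
})

test_that("TPG and PVR arithmetic", {
  r <- tpg_pvr(18.5, 5.3, 7.5)
  expect_equal(r$TPG_mmHg, 13.2)
  expect_equal(r$PVR_mmHg_min_L, 13.2 / 7.5)
  expect_equal(tpg_pvr(10, 10, 5)$TPG_mmHg, 0)
  expect_equal(tpg_pvr(10, 10, 5)$PVR_mmHg_min_L, 0)
  expect_equal(tpg_pvr(20, 8, 6)$PVR_mmHg_min_L,
               2 * tpg_pvr(20, 8, 12)$PVR_mmHg_min_L)
  expect_error(tpg_pvr(10, 5, 0), "positive")
})

test_that("venous wave features recover constructed peaks exactly", {
  period <- 0.8; n <- 800
  t <- (0:(n - 1)) / n * period
  bump <- function(c0, w, h) h * exp(-((t - c0) / w)^2)
  q <- (bump(0.10, 0.03, 60) + bump(0.30, 0.03, 80) +
        bump(0.50, 0.04, 90) - bump(0.74, 0.02, 30)) * 1e-6
  ft <- venous_wave_features(q, period)
  expect_true(all(ft$present))
  expect_equal(ft$t_peak[ft$wave == "S1"], 0.10, tolerance = 2e-2)
  expect_equal(ft$t_peak[ft$wave == "S2"], 0.30, tolerance = 2e-2)
  expect_equal(ft$t_peak[ft$wave == "D"], 0.50, tolerance = 2e-2)
  expect_equal(ft$peak_mL_s[ft$wave == "D"], 90, tolerance = 1e-2)
  expect_lt(ft$peak_mL_s[ft$wave == "AR"], 0)
  # monotone systolic rise (no S1) and no late reversal
  q2 <- (bump(0.30, 0.05, 80) + bump(0.50, 0.04, 90)) * 1e-6
  ft2 <- venous_wave_features(q2, period)
  expect_false(ft2$present[ft2$wave == "S1"])
  expect_false(ft2$present[ft2$wave == "AR"])
  expect_true(ft2$present[ft2$wave == "S2"])
})
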