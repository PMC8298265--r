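test_that("network build reproduces the geometry table and validates it", {
  net <- build_network()
  v <- net$vessels
  expect_equal(nrow(v), 11)
  expect_equal(v$length_cm[v$name == "MPA"], 4.5)
  expect_equal(v$prox_r_cm[v$name == "MPA"], 3.1 / 2)
  expect_equal(v$dist_r_cm[v$name == "MPA"], 3.0 / 2)
  expect_equal(v$prox_r_cm[v$name == "LIPV"], 1.6 / 2)
  expect_equal(v$length_cm[v$name == "LIPV"], 1.8)
  # grid covers [0, L] with the requested spacing
  expect_equal(v$n[v$name == "MPA"], 4.5 / 0.05 + 1)
  # taper: R0 interpolates proximal -> distal radius
  i <- net$vessels$i0[1]:net$vessels$i1[1]
  expect_equal(net$R0[i[1]], cm_to_m(1.55))
  expect_equal(net$R0[i[length(i)]], cm_to_m(1.50))
  expect_true(all(abs(diff(diff(net$R0[i]))) < 1e-12))
  # tree interfaces pair terminal arteries with their veins
  expect_equal(net$interfaces$vein[net$interfaces$artery == "LIA"], "LIPV")
  expect_equal(net$interfaces$r_root_a[net$interfaces$artery == "LIA"], 0.75)
  expect_equal(net$interfaces$r_root_v[net$interfaces$artery == "LIA"], 0.80)
  geo <- pulmonary_geometry()
  expect_error(build_network(geo[geo$name != "LPA", ]), "LPA")
  geo2 <- pulmonary_geometry(); geo2$length_cm[2] <- -1
  expect_error(build_network(geo2), "RPA")
})

test_that("the rest state is a fixed point of the interior scheme", {
  net <- toy_fixture("single-vessel", dx_cm = 0.2)
  bc <- list(inlet = list(type = "q", fn = function(t) 0),
             outlet = list(type = "p", fn = function(t) 0))
  run <- run_to_periodic(net, bc, dt = 1e-4, steps_per_cycle = 200L,
                         cycles = 2, tol = 1e-12, min_cycles = 1,
                         init = list(p_art = 0, p_vein = 0))
  expect_equal(run$state$A, net$A0, tolerance = 1e-12)
  expect_equal(max(abs(run$state$q)), 0, tolerance = 1e-15)
})

test_that("a small pressure pulse propagates at the tube-law wave speed", {
  net <- vessel_network(
    data.frame(name = "V", type = "artery", prox_diam_cm = 1,
               dist_diam_cm = 1, length_cm = 50), dx_cm = 0.1)
  x <- seq(0, 50, by = 0.1)
  p_init <- mmHg_to_Pa(0.5) * exp(-((x - 15) / 2)^2)
  A_init <- net$A0 * (1 + p_init / net$f)^2
  bc <- list(inlet = list(type = "q", fn = function(t) 0),
             outlet = list(type = "p", fn = function(t) 0))
  tend <- 0.02
  run <- run_to_periodic(net, bc, dt = 2e-5, steps_per_cycle = 1000L,
                         cycles = 1, tol = 0, min_cycles = 1,
                         eps = 1e9,      # friction switched off
                         warm = list(A = A_init, q = numeric(length(x)),
                                     zeta = 0, q_valve = 0))
  # the rightward half-pulse peak moves by c * t
  pf <- .p_of(net, run$state$A)
  sel <- x > 16
  peak_x <- x[sel][which.max(pf[sel])]
  c0 <- wave_speed(net$A0[1], list(A0 = net$A0[1], EhR0 = net$f[1] * 3 / 4),
                   net$fluid)
  expect_equal((peak_x - 15) / 100 / tend, c0, tolerance = 0.02)
})

test_that("friction balances the pressure gradient in steady flow", {
  net <- toy_fixture("single-vessel", dx_cm = 0.2)   # r = 0.5 cm, L = 10 cm
  q0 <- 20e-6
  bc <- list(inlet = list(type = "q", fn = function(t) q0),
             outlet = list(type = "p", fn = function(t) mmHg_to_Pa(10)))
  # start from the approximate analytic steady state; the run keeps it
  x <- seq(0, 0.1, by = 0.002)
  eps0 <- boundary_layer_thickness(0.2, net$fluid)
  A_out <- tube_law_area(mmHg_to_Pa(10),
                         list(A0 = net$A0[1], f = net$f[1], p0 = 0))
  g0 <- 2 * pi * net$fluid$nu * net$fluid$rho * sqrt(A_out / pi) * q0 /
    (eps0 * A_out^2)
  p_ss <- mmHg_to_Pa(10) + g0 * (0.1 - x)
  A_ss <- net$A0 * (1 + p_ss / net$f)^2
  run <- suppressWarnings(
    run_to_periodic(net, bc, dt = 1e-4, steps_per_cycle = 2000L,
                    cycles = 10, tol = 1e-8,
                    warm = list(A = A_ss, q = rep(q0, length(x)),
                                zeta = 0, q_valve = 0)))
  eps <- run$eps
  A <- run$state$A
  p <- .p_of(net, A)
  # analytic steady gradient: dp/dx = 2 pi nu rho R q / (eps A^2)
  nu <- net$fluid$nu; rho <- net$fluid$rho
  dpdx <- 2 * pi * nu * rho * sqrt(mean(A) / pi) * q0 / (eps * mean(A)^2)
  expect_equal(p[1] - p[length(p)], dpdx * 0.1, tolerance = 0.02)
  # residual standing-wave ripple decays below 0.5% of the through-flow
  expect_equal(max(abs(run$state$q - q0)) / q0, 0, tolerance = 5e-3)
})

test_that("identical daughters split the parent flow exactly in half", {
  net <- toy_fixture("y-junction", dx_cm = 0.2)
  qfn <- function(t) 50e-6 * (1 + sin(2 * pi * t / 0.4))
  bc <- list(inlet = list(type = "q", fn = qfn),
             outlet = list(type = "p", fn = function(t) mmHg_to_Pa(5)))
  run <- suppressWarnings(
    run_to_periodic(net, bc, dt = 1e-4, steps_per_cycle = 4000L,
                    cycles = 6, tol = 1e-4,
                    init = list(p_art = mmHg_to_Pa(5.5))))
  i1 <- match("D1", run$vessels); i2 <- match("D2", run$vessels)
  expect_equal(run$probe_q[, i1], run$probe_q[, i2], tolerance = 1e-12)
  # junction mass residual is at solver precision throughout
  st <- run$state
  jp <- net$junctions$p_end
  expect_lt(abs(st$q[jp] - st$q[net$junctions$d1_start] -
                st$q[net$junctions$d2_start]), 1e-12 * abs(st$q[jp]) + 1e-18)
  expect_lt(run$junction_residual_max, 1e-12)
  # pressure is continuous across the junction
  pj <- .p_of(net, st$A, c(jp, net$junctions$d1_start, net$junctions$d2_start))
  expect_lt(diff(range(pj)), 1e-8)
})

test_that("the inlet valve blocks backflow and follows the orifice law", {
  net <- toy_fixture("single-vessel", dx_cm = 0.2)
  vl <- valve_params(annulus_area_cm2 = pi * 0.5^2)
  # upstream pressure below the vessel pressure: valve stays shut
  bc <- list(inlet = list(type = "valve", p_fn = function(t) mmHg_to_Pa(2),
                          valve = vl),
             outlet = list(type = "p", fn = function(t) mmHg_to_Pa(10)))
  run <- run_to_periodic(net, bc, dt = 1e-4, steps_per_cycle = 1000L,
                         cycles = 2, tol = 1e-9, min_cycles = 1,
                         init = list(p_art = mmHg_to_Pa(10)))
  expect_equal(max(run$q_inlet), 0)
  expect_equal(max(run$zeta), 0)
  # constant favourable gradient: steady Bernoulli balance dp = B q^2
  bc2 <- list(inlet = list(type = "valve", p_fn = function(t) mmHg_to_Pa(20),
                           valve = vl),
              outlet = list(type = "p", fn = function(t) mmHg_to_Pa(10)))
  run2 <- run_to_periodic(net, bc2, dt = 1e-4, steps_per_cycle = 2000L,
                          cycles = 10, tol = 1e-10,
                          init = list(p_art = mmHg_to_Pa(10)))
  q_ss <- run2$state$q_valve
  expect_gt(q_ss, 0)
  expect_equal(utils::tail(run2$zeta, 1), 1, tolerance = 1e-6)
  dp_valve <- mmHg_to_Pa(20) - .p_of(net, run2$state$A, 1)
  expect_equal(dp_valve, vl$B * q_ss^2, tolerance = 1e-3)
})

test_that("static boundary conditions settle within three cycles", {
  net <- toy_fixture("single-vessel", dx_cm = 0.2)
  bc <- list(inlet = list(type = "q", fn = function(t) 50e-6),
             outlet = list(type = "p", fn = function(t) mmHg_to_Pa(10)))
  x <- seq(0, 0.1, by = 0.002)
  eps0 <- boundary_layer_thickness(0.2, net$fluid)
  A_out <- tube_law_area(mmHg_to_Pa(10),
                         list(A0 = net$A0[1], f = net$f[1], p0 = 0))
  g0 <- 2 * pi * net$fluid$nu * net$fluid$rho * sqrt(A_out / pi) * 50e-6 /
    (eps0 * A_out^2)
  p_ss <- mmHg_to_Pa(10) + g0 * (0.1 - x)
  A_ss <- net$A0 * (1 + p_ss / net$f)^2
  run <- run_to_periodic(net, bc, dt = 1e-4, steps_per_cycle = 2000L,
                         cycles = 6, tol = 1e-3,
                         warm = list(A = A_ss, q = rep(50e-6, length(x)),
                                     zeta = 0, q_valve = 0))
  expect_true(run$converged)
  expect_lte(run$cycles_run, 3)
})

test_that("the interior scheme is second order on a smooth pulse", {
  ref_dx <- 0.025
  solve_at <- function(dx) {
    net <- vessel_network(
      data.frame(name = "V", type = "artery", prox_diam_cm = 1,
                 dist_diam_cm = 1, length_cm = 40), dx_cm = dx)
    x <- seq(0, 40, by = dx)
    p_init <- mmHg_to_Pa(1) * exp(-((x - 12) / 1.5)^2)
    A_init <- net$A0 * (1 + p_init / net$f)^2
    bc <- list(inlet = list(type = "q", fn = function(t) 0),
               outlet = list(type = "p", fn = function(t) 0))
    run <- run_to_periodic(net, bc, dt = 1e-5, steps_per_cycle = 800L,
                           cycles = 1, tol = 0, min_cycles = 1, eps = 1e9,
                           warm = list(A = A_init, q = numeric(length(x)),
                                       zeta = 0, q_valve = 0))
    list(x = x, A = run$state$A / net$A0)
  }
  ref <- solve_at(ref_dx)
  err <- vapply(c(0.4, 0.2, 0.1), function(dx) {
    s <- solve_at(dx)
    idx <- match(round(s$x / ref_dx), round(ref$x / ref_dx))
    sqrt(mean((s$A - ref$A[idx])^2))
  }, numeric(1))
  rate <- log2(err[1] / err[2])
  rate2 <- log2(err[2] / err[3])
  expect_gt(rate, 1.8)
  expect_gt(rate2, 1.8)
})
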