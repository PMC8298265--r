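fl <- fluid_properties()

test_that("tree generation follows the radius scaling and cutoff", {
  tr <- generate_tree(tree_spec(0.05))
  # deepest alpha-only path: 0.05 * 0.91^29 >= 0.003 > 0.05 * 0.91^30
  expect_equal(max(tr$a[tr$b == 0]), 29)
  # deepest beta-only path: 0.05 * 0.58^5 >= 0.003 > 0.05 * 0.58^6
  expect_equal(max(tr$b[tr$a == 0]), 5)
  expect_true(all(tr$radius_cm >= 0.003))
  # daughters of a parent of radius 0.1 cm
  tr2 <- generate_tree(tree_spec(0.1))
  expect_equal(tr2$radius_cm[tr2$a == 1 & tr2$b == 0], 0.091)
  expect_equal(tr2$radius_cm[tr2$a == 0 & tr2$b == 1], 0.058)
  # multiplicities are binomial coefficients
  expect_equal(tr$multiplicity, choose(tr$a + tr$b, tr$b))
  # lengths follow the length-to-radius ratio
  expect_equal(tr$length_cm, 12.4 * tr$radius_cm)
  # stiffness matches the small-vessel law
  expect_equal(tr$EhR0_mmHg, small_vessel_stiffness(tr$radius_cm))
  expect_error(tree_spec(0.001), "empty tree")
  expect_error(tree_spec(0.05, alpha = 0.5, beta = 0.6), "beta < alpha")
})

test_that("single-vessel two-port has the Poiseuille and zero-length limits", {
  mu <- fl$mu
  r <- 0.003; L <- 12.4 * r
  M0 <- vessel_two_port(0, r, L, fl)
  Rp <- 8 * mu * cm_to_m(L) / (pi * cm_to_m(r)^4)
  expect_equal(Re(M0[1, 2]), Rp, tolerance = 1e-12)
  expect_equal(Re(M0[1, 1]), 1); expect_equal(Re(M0[2, 1]), 0)
  # L -> 0 gives the identity at any frequency
  Mz <- vessel_two_port(2 * pi * 5, 0.01, 1e-9, fl)
  expect_equal(abs(Mz[1, 1] - 1), 0, tolerance = 1e-6)
  expect_lt(abs(Mz[1, 2]), 1e-3 * abs(M0[1, 2]))
  # determinant is exactly 1 (reciprocity), also in the nearly
  # lossless limit of vanishing viscosity
  det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  fl_thin <- fluid_properties(mu = 1e-9)
  M <- vessel_two_port(2 * pi * 3, 0.01, 0.124, fl_thin)
  expect_equal(abs(det2(M)), 1, tolerance = 1e-8)
  M <- vessel_two_port(2 * pi * 7, 0.05, 0.5, fl)
  expect_equal(abs(det2(M) - 1), 0, tolerance = 1e-8)
})

# independent oracle: full binary-tree recursion, one node at a time,
# with no (a, b) collapsing and no memoisation
brute_force_dc_resistance <- function(spec, fluid) {
  rv <- function(r) 8 * fluid$mu * cm_to_m(spec$lrr * r) / (pi * cm_to_m(r)^4)
  rec <- function(ra, rb) {
    own <- rv(ra) + rv(rb)
    oa <- ra * spec$alpha >= spec$r_min
    ob <- ra * spec$beta >= spec$r_min
    if (!oa && !ob) return(own)
    if (!ob) return(own + rec(ra * spec$alpha, rb * spec$alpha))
    own + 1 / (1 / rec(ra * spec$alpha, rb * spec$alpha) +
               1 / rec(ra * spec$beta, rb * spec$beta))
  }
  rec(spec$r_root_a, spec$r_root_v)
}

brute_force_two_port <- function(spec, omega, fluid) {
  chain <- function(m1, m2) m1 %*% m2
  par2 <- function(m1, m2) {
    toy <- function(m) {
      d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
      matrix(c(m[2, 2] / m[1, 2], -1 / m[1, 2],
               -d / m[1, 2], m[1, 1] / m[1, 2]), 2, 2)
    }
    y <- toy(m1) + toy(m2)
    d <- y[1, 1] * y[2, 2] - y[1, 2] * y[2, 1]
    matrix(c(-y[2, 2] / y[2, 1], -d / y[2, 1],
             -1 / y[2, 1], -y[1, 1] / y[2, 1]), 2, 2)
  }
  rec <- function(ra, rb) {
    Ma <- vessel_two_port(omega, ra, spec$lrr * ra, fluid)
    Mv <- vessel_two_port(omega, rb, spec$lrr * rb, fluid)
    oa <- ra * spec$alpha >= spec$r_min
    ob <- ra * spec$beta >= spec$r_min
    inner <- if (!oa && !ob) diag(2)
             else if (!ob) rec(ra * spec$alpha, rb * spec$alpha)
             else par2(rec(ra * spec$alpha, rb * spec$alpha),
                       rec(ra * spec$beta, rb * spec$beta))
    chain(chain(Ma, inner), Mv)
  }
  rec(spec$r_root_a, spec$r_root_v)
}

test_that("DC tree conductance equals brute-force Poiseuille enumeration", {
  spec <- tree_spec(0.01, 0.012)
  expect_lte(sum(generate_tree(spec)$multiplicity), 100)  # enumerable fixture
  adm <- tree_admittance(spec, period = 0.8, n_harmonics = 4)
  R_brute <- brute_force_dc_resistance(spec, fl)
  expect_equal(Re(adm$Y11[1]), 1 / R_brute, tolerance = 1e-10)
  expect_equal(Im(adm$Y11[1]), 0)
  # at DC the network stores nothing: flow in = flow out
  expect_equal(adm$Y21[1], adm$Y11[1], tolerance = 1e-12)
  # doubling viscosity halves the DC conductance
  adm2 <- tree_admittance(spec, period = 0.8, n_harmonics = 0,
                          fluid = fluid_properties(mu = 2 * fl$mu))
  expect_equal(Re(adm2$Y11[1]), Re(adm$Y11[1]) / 2, tolerance = 1e-12)
})

test_that("memoised composition equals explicit tree enumeration off DC", {
  spec <- tree_spec(0.01, 0.015)   # three pure-beta generations
  adm <- tree_admittance(spec, period = 0.8, n_harmonics = 8)
  for (k in c(1, 4, 8)) {
    omega <- 2 * pi * k / 0.8
    M <- brute_force_two_port(spec, omega, fl)
    d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    expect_equal(adm$Y11[k + 1], M[2, 2] / M[1, 2], tolerance = 1e-12)
    expect_equal(adm$Y12[k + 1], -d / M[1, 2], tolerance = 1e-12)
    expect_equal(adm$Y21[k + 1], 1 / M[1, 2], tolerance = 1e-12)
    expect_equal(adm$Y22[k + 1], -M[1, 1] / M[1, 2], tolerance = 1e-12)
  }
})

test_that("admittance is reciprocal, passive and mirror-symmetric", {
  spec <- tree_spec(0.02, 0.02)    # identical arterial and venous trees
  adm <- tree_admittance(spec, period = 0.8, n_harmonics = 32)
  # through-flow reciprocity
  expect_equal(max(abs(adm$Y12 + adm$Y21) / abs(adm$Y21)), 0, tolerance = 1e-10)
  # mirror symmetry: swapping ports (with the sign convention flipped)
  # leaves the matrix unchanged: Y11 = -Y22
  expect_equal(max(abs(adm$Y11 + adm$Y22) / abs(adm$Y11)), 0, tolerance = 1e-10)
  # |Y| bounded; Y(0) real and positive as a conductance
  expect_true(all(is.finite(abs(adm$Y11)) & is.finite(abs(adm$Y12))))
  expect_gt(Re(adm$Y11[1]), 0)
  # passivity: hermitian part of the currents-into-network form is PSD
  for (k in c(1, 5, 17, 33)) {
    Y <- matrix(c(adm$Y11[k], -adm$Y21[k], adm$Y12[k], -adm$Y22[k]), 2, 2)
    H <- (Y + Conj(t(Y))) / 2
    ev <- eigen(H, only.values = TRUE)$values
    expect_true(all(Re(ev) > -1e-9 * max(abs(ev))))
  }
})

test_that("periodic terminal update reproduces DC and single-harmonic forms", {
  spec <- tree_spec(0.05, 0.06)
  adm <- tree_admittance(spec, period = 0.8, n_harmonics = 16)
  n <- 128
  t <- (0:(n - 1)) / n * 0.8
  pbar <- mmHg_to_Pa(15); pv <- mmHg_to_Pa(5)
  # constant pressures: steady flows from Y(0), no storage
  res <- terminal_bc_step(rep(pbar, n), rep(pv, n), adm)
  q0 <- Re(adm$Y11[1]) * pbar + Re(adm$Y12[1]) * pv
  expect_equal(res$q_a, rep(q0, n), tolerance = 1e-12)
  expect_equal(mean(res$q_a), mean(res$q_v), tolerance = 1e-12)
  # single harmonic on the arterial side
  delta <- mmHg_to_Pa(2); om1 <- 2 * pi / 0.8
  pa <- pbar + delta * sin(om1 * t)
  res <- terminal_bc_step(pa, rep(pv, n), adm)
  qa_ac <- res$q_a - (Re(adm$Y11[1]) * pbar + Re(adm$Y12[1]) * pv)
  # quadrature fit recovers amplitude delta |Y11(om1)| and phase arg Y11
  fitc <- sum(qa_ac * cos(om1 * t)) * 2 / n
  fits <- sum(qa_ac * sin(om1 * t)) * 2 / n
  expect_equal(sqrt(fitc^2 + fits^2) / (delta * abs(adm$Y11[2])), 1,
               tolerance = 1e-9)
  expect_equal(atan2(fitc, fits), Arg(adm$Y11[2]), tolerance = 1e-9)
  # mass balance over a period at periodic state
  expect_lt(abs(mean(res$q_a) - mean(res$q_v)), 1e-8 * abs(mean(res$q_a)))
  expect_error(terminal_bc_step(1, 1, adm), "full period")
})

test_that("admittance converges in the harmonic count", {
  spec <- tree_spec(0.05, 0.05)
  a64 <- tree_admittance(spec, 0.8, 64)
  a128 <- tree_admittance(spec, 0.8, 128)
  # shared harmonics agree exactly; the tail is small relative to Y(0)
  expect_equal(a128$Y11[1:65], a64$Y11, tolerance = 1e-12)
  expect_lt(abs(a128$Y11[129]) / abs(a128$Y11[1]), 10)
})

test_that("branch pressure profile is monotone and mass-consistent at DC", {
  spec <- tree_spec(0.05, 0.05)
  adm <- tree_admittance(spec, period = 0.8, n_harmonics = 8)
  n <- 64
  pa <- rep(mmHg_to_Pa(18), n); pv <- rep(mmHg_to_Pa(5), n)
  prof <- branch_pressure_profile(adm, pa, pv, path = "alpha")
  # arterial pressure decreases monotonically along the path
  expect_true(all(diff(prof$mean_p_art_mmHg) < 0))
  # venous pressure decreases towards the venous root
  expect_true(all(diff(prof$mean_p_ven_mmHg) > 0))
  expect_equal(attr(prof, "drop_arterial_mmHg") + attr(prof, "drop_venous_mmHg"),
               18 - 5, tolerance = 1e-9)
  # last alpha-path radius is still above cutoff
  expect_gte(min(prof$radius_cm), spec$r_min)
  # single-vessel path: midpoint pressure is root minus half the drop
  spec1 <- tree_spec(0.0032, 0.0032)
  adm1 <- tree_admittance(spec1, period = 0.8, n_harmonics = 2)
  pr1 <- branch_pressure_profile(adm1, rep(mmHg_to_Pa(10), 16),
                                 rep(mmHg_to_Pa(2), 16))
  expect_equal(nrow(pr1), 1)
  drop_a <- 10 - attr(pr1, "cutoff_p_mmHg")
  expect_equal(pr1$mean_p_art_mmHg, 10 - drop_a / 2, tolerance = 1e-9)
  # beta path stays above cutoff too
  profb <- branch_pressure_profile(adm, pa, pv, path = "beta")
  expect_gte(min(profb$radius_cm), spec$r_min)
  expect_true(all(diff(profb$mean_p_art_mmHg) < 0))
})

test_that("tree CSV and admittance JSON exports round-trip", {
  spec <- tree_spec(0.01)
  tr <- generate_tree(spec)
  f <- tempfile(fileext = ".csv")
  write_tree_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(back$radius_cm, tr$radius_cm, tolerance = 1e-12)
  expect_equal(names(back), c("a", "b", "multiplicity", "radius_cm",
                              "length_cm", "EhR0_mmHg"))
  adm <- tree_admittance(spec, 0.8, 4)
  fj <- tempfile(fileext = ".json")
  write_admittance_json(adm, fj)
  obj <- jsonlite::read_json(fj)
  expect_equal(length(obj$Y11), 5)
  expect_equal(obj$Y11[[2]][[1]], Re(adm$Y11[2]), tolerance = 1e-12)
  expect_equal(obj$Y11[[2]][[2]], Im(adm$Y11[2]), tolerance = 1e-12)
})
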