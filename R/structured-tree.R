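#' Specification of a mirrored arterial-venous structured tree
#'
#' A structured tree is a self-similar binary tree in which each parent
#' vessel of radius r spawns daughters of radius `alpha * r` and
#' `beta * r`, truncated at a minimum radius.  The venous side is a
#' mirror image of the arterial side in terms of generations: same
#' topology, radii scaled from the venous root radius, joined to the
#' arterial side vessel-by-vessel at the terminal generations.  Vessel
#' length follows a length-to-radius ratio, and wall stiffness follows
#' the radius-dependent law [small_vessel_stiffness()].
#'
#' @param r_root_a arterial root radius in cm.
#' @param r_root_v venous root radius in cm.
#' @param alpha,beta daughter radius scaling factors (0 < beta < alpha < 1).
#' @param r_min cutoff radius in cm; vessels whose radius would fall
#'   below it are neglected (default 0.003 cm = 30 microns).
#' @param lrr length-to-radius ratio (dimensionless).
#' @return an object of class `tree_spec`.
#' @export
tree_spec <- function(r_root_a, r_root_v = r_root_a, alpha = 0.91,
                      beta = 0.58, r_min = 0.003, lrr = 12.4) {
  if (!(beta > 0 && beta < alpha && alpha < 1)) stop("need 0 < beta < alpha < 1")
  if (r_min <= 0) stop("r_min must be positive")
  if (r_root_a < r_min) stop("empty tree: root radius below cutoff")
  structure(list(r_root_a = r_root_a, r_root_v = r_root_v, alpha = alpha,
                 beta = beta, r_min = r_min, lrr = lrr),
            class = "tree_spec")
}

#' Generate the occupied cells of a structured tree
#'
#' Nodes are never enumerated individually: all vessels that have taken
#' `a` alpha-steps and `b` beta-steps from the root are identical, so
#' the tree is represented by its occupied `(a, b)` cells with
#' multiplicity `choose(a + b, b)`.  A cell is occupied when the
#' arterial radius `alpha^a beta^b r_root_a` is at least the cutoff.
#'
#' @param spec a [tree_spec()].
#' @return a data.frame with columns `a`, `b`, `multiplicity`,
#'   `radius_cm`, `length_cm`, `EhR0_mmHg` (arterial side) and
#'   `radius_v_cm`, `length_v_cm`, `EhR0_v_mmHg` (venous mirror), plus a
#'   logical `terminal` flag (both daughters below cutoff).
#' @examples
#' tr <- generate_tree(tree_spec(0.05))
#' max(tr$a[tr$b == 0]) # 29: the deepest alpha-only path has 30 vessels
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  amax <- floor(log(spec$r_min / spec$r_root_a) / log(spec$alpha))
  cells <- NULL
  for (b in 0:1000) {
    rb <- spec$r_root_a * spec$beta^b
    if (rb < spec$r_min) break
    a_top <- floor(log(spec$r_min / rb) / log(spec$alpha))
    # guard against rounding at the boundary
    while (rb * spec$alpha^(a_top + 1) >= spec$r_min) a_top <- a_top + 1
    while (a_top >= 0 && rb * spec$alpha^a_top < spec$r_min) a_top <- a_top - 1
    if (a_top < 0) break
    cells <- rbind(cells, data.frame(a = 0:a_top, b = b))
  }
  r_a <- spec$r_root_a * spec$alpha^cells$a * spec$beta^cells$b
  r_v <- spec$r_root_v * spec$alpha^cells$a * spec$beta^cells$b
  occ <- function(a, b) spec$r_root_a * spec$alpha^a * spec$beta^b >= spec$r_min
  data.frame(
    a = cells$a, b = cells$b,
    multiplicity = choose(cells$a + cells$b, cells$b),
    radius_cm = r_a, length_cm = spec$lrr * r_a,
    EhR0_mmHg = small_vessel_stiffness(r_a),
    radius_v_cm = r_v, length_v_cm = spec$lrr * r_v,
    EhR0_v_mmHg = small_vessel_stiffness(r_v),
    terminal = !occ(cells$a + 1, cells$b) & !occ(cells$a, cells$b + 1)
  )
}

#' Frequency-domain two-port of a single small vessel
#'
#' Closed-form transmission matrix of the linearised wave equations in a
#' compliant vessel with a Womersley radial velocity profile.  With
#' complex wave speed `c_w = sqrt(A0 (1 - F_J) / (rho C))` and
#' characteristic admittance `g = C c_w`, the matrix is
#' `[[cos(th), i sin(th)/g], [i g sin(th), cos(th)]]`, `th = omega L / c_w`,
#' mapping `[p; q]` at the downstream end to the upstream end.  At
#' `omega = 0` it reduces to a series Poiseuille resistance
#' `8 mu L / (pi r^4)`.
#'
#' @param omega angular frequency in rad/s (scalar or vector).
#' @param r_cm vessel radius in cm.
#' @param L_cm vessel length in cm.
#' @param fluid a [fluid_properties()].
#' @param EhR0_mmHg wall stiffness in mmHg; default from
#'   [small_vessel_stiffness()] at this radius.
#' @return for scalar `omega` a 2x2 complex matrix; otherwise a list of
#'   vectors `A`, `B`, `C`, `D` over the frequency grid.
#' @export
vessel_two_port <- function(omega, r_cm, L_cm = NULL, fluid = fluid_properties(),
                            EhR0_mmHg = small_vessel_stiffness(r_cm)) {
  if (any(omega < 0)) stop("omega must be non-negative")
  if (is.null(L_cm)) L_cm <- 12.4 * r_cm
  r <- cm_to_m(r_cm); L <- cm_to_m(L_cm)
  A0 <- pi * r^2
  Cc <- 3 * A0 / (2 * mmHg_to_Pa(EhR0_mmHg))   # compliance per length
  Ae <- De <- rep(1 + 0i, length(omega))
  Be <- rep(8 * fluid$mu * L / (pi * r^4) + 0i, length(omega))
  Ce <- rep(0 + 0i, length(omega))
  pos <- omega > 0
  if (any(pos)) {
    w <- omega[pos]
    fj <- womersley_fj(r * sqrt(w / fluid$nu))
    cw <- sqrt(A0 * (1 - fj) / (fluid$rho * Cc))
    g <- Cc * cw
    th <- w * L / cw
    Ae[pos] <- De[pos] <- cos(th)
    Be[pos] <- 1i * sin(th) / g
    Ce[pos] <- 1i * g * sin(th)
  }
  if (length(omega) == 1L)
    matrix(c(Ae, Ce, Be, De), 2, 2)
  else list(A = Ae, B = Be, C = Ce, D = De)
}

# --- two-port algebra on ABCD component lists (vectors over frequency) ---

.tp_chain <- function(m1, m2) {
  list(A = m1$A * m2$A + m1$B * m2$C,
       B = m1$A * m2$B + m1$B * m2$D,
       C = m1$C * m2$A + m1$D * m2$C,
       D = m1$C * m2$B + m1$D * m2$D)
}

.tp_to_y <- function(m) {
  det <- m$A * m$D - m$B * m$C
  list(Y11 = m$D / m$B, Y12 = -det / m$B, Y21 = -1 / m$B, Y22 = m$A / m$B)
}

.tp_from_y <- function(y) {
  det <- y$Y11 * y$Y22 - y$Y12 * y$Y21
  list(A = -y$Y22 / y$Y21, B = -1 / y$Y21, C = -det / y$Y21, D = -y$Y11 / y$Y21)
}

.tp_parallel <- function(m1, m2) {
  y1 <- .tp_to_y(m1); y2 <- .tp_to_y(m2)
  .tp_from_y(list(Y11 = y1$Y11 + y2$Y11, Y12 = y1$Y12 + y2$Y12,
                  Y21 = y1$Y21 + y2$Y21, Y22 = y1$Y22 + y2$Y22))
}

.tp_identity <- function(n) {
  list(A = rep(1 + 0i, n), B = rep(0 + 0i, n),
       C = rep(0 + 0i, n), D = rep(1 + 0i, n))
}

# dynamic-programming composition of the mirrored tree pair: the subtree
# rooted at cell (a, b) is identical wherever it occurs, so its two-port is
# memoised on (a, b).  Returns the ABCD components of the root-to-root
# two-port over the frequency grid.
.tree_two_port <- function(spec, omega, fluid) {
  n <- length(omega)
  memo <- new.env(parent = emptyenv())
  occ <- function(a, b) spec$r_root_a * spec$alpha^a * spec$beta^b >= spec$r_min
  rec <- function(a, b) {
    key <- paste0(a, ",", b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    sc <- spec$alpha^a * spec$beta^b
    ra <- spec$r_root_a * sc; rv <- spec$r_root_v * sc
    Ma <- vessel_two_port(omega, ra, spec$lrr * ra, fluid)
    Mv <- vessel_two_port(omega, rv, spec$lrr * rv, fluid)
    if (n == 1L) { Ma <- list(A = Ma[1,1] + 0i, B = Ma[1,2] + 0i, C = Ma[2,1] + 0i, D = Ma[2,2] + 0i)
                   Mv <- list(A = Mv[1,1] + 0i, B = Mv[1,2] + 0i, C = Mv[2,1] + 0i, D = Mv[2,2] + 0i) }
    oa <- occ(a + 1, b); ob <- occ(a, b + 1)
    inner <- if (oa && ob) .tp_parallel(rec(a + 1, b), rec(a, b + 1))
             else if (oa) rec(a + 1, b)
             else .tp_identity(n)   # terminal: direct arterial-venous junction
    res <- .tp_chain(.tp_chain(Ma, inner), Mv)
    memo[[key]] <- res
    res
  }
  rec(0, 0)
}

#' Two-port admittance of a mirrored structured-tree pair
#'
#' Composes the single-vessel two-ports through the bifurcating arterial
#' tree, across the cutoff junctions and back up the mirrored venous
#' tree, memoised on the generation cell `(a, b)` (all subtrees rooted at
#' the same cell are identical), at the harmonics `omega_k = 2 pi k / T`,
#' `k = 0 .. n_harmonics`.
#'
#' The returned matrices satisfy
#' `[Q_a(w); Q_v(w)] = Y(w) [P_a(w); P_v(w)]`
#' with `Q_a` positive into the tree at the arterial root and `Q_v`
#' positive out of the tree at the venous root (i.e. both flows measured
#' in the direction of mean perfusion).  With this through-flow
#' convention the reciprocity of the passive vessel network appears as
#' `Y12 = -Y21`; the conventional symmetric form is recovered by
#' flipping the sign of the venous port current.
#'
#' @param spec a [tree_spec()].
#' @param period fundamental period T in s.
#' @param n_harmonics number of positive harmonics K (default 512).
#' @param fluid a [fluid_properties()].
#' @return an object of class `tree_admittance`: list with `omega`,
#'   `period`, complex vectors `Y11`, `Y12`, `Y21`, `Y22` of length
#'   `n_harmonics + 1`, and the generating `spec`.
#' @export
tree_admittance <- function(spec, period = 0.8, n_harmonics = 512,
                            fluid = fluid_properties()) {
  stopifnot(inherits(spec, "tree_spec"), period > 0, n_harmonics >= 0)
  omega <- 2 * pi * (0:n_harmonics) / period
  tp <- .tree_two_port(spec, omega, fluid)
  det <- tp$A * tp$D - tp$B * tp$C
  bad <- !is.finite(tp$B) | abs(tp$B) == 0
  if (any(bad))
    stop("singular tree composition at harmonic(s) ", paste(which(bad) - 1, collapse = ", "))
  structure(list(omega = omega, period = period,
                 Y11 = tp$D / tp$B, Y12 = -det / tp$B,
                 Y21 = 1 / tp$B, Y22 = -tp$A / tp$B,
                 abcd = tp, spec = spec, fluid = fluid),
            class = "tree_admittance")
}

#' Periodic terminal boundary update from tree admittance
#'
#' Applies the two-port admittance to one full period of uniformly
#' sampled root pressures by per-harmonic multiplication, returning the
#' corresponding real flow series.  Harmonics beyond those stored in
#' `adm` are dropped (the tree is a low-pass load; convergence in the
#' harmonic count is part of the test suite).
#'
#' @param p_a,p_v arterial / venous root pressure over exactly one
#'   period, in Pa, uniformly sampled (equal lengths).
#' @param adm a [tree_admittance()].
#' @return list with elements `q_a`, `q_v` in m^3/s.
#' @export
terminal_bc_step <- function(p_a, p_v, adm) {
  stopifnot(inherits(adm, "tree_admittance"))
  n <- length(p_a)
  if (length(p_v) != n) stop("pressure histories must have equal length")
  if (n < 2) stop("pressure history must cover one full period")
  ker <- admittance_kernel(adm, n)
  Pa <- stats::fft(p_a); Pv <- stats::fft(p_v)
  qa <- Re(stats::fft(ker$H11 * Pa + ker$H12 * Pv, inverse = TRUE)) / n
  qv <- Re(stats::fft(ker$H21 * Pa + ker$H22 * Pv, inverse = TRUE)) / n
  list(q_a = qa, q_v = qv)
}

# full-length hermitian transfer vectors (and real time-domain kernels)
# for an n-sample period
admittance_kernel <- function(adm, n) {
  K <- length(adm$omega) - 1L
  kmax <- min(K, floor((n - 1) / 2))
  fill <- function(Y) {
    H <- complex(n)
    H[1] <- Y[1]
    if (kmax >= 1) {
      H[2:(kmax + 1)] <- Y[2:(kmax + 1)]
      H[n:(n - kmax + 1)] <- Conj(Y[2:(kmax + 1)])
    }
    H
  }
  H11 <- fill(adm$Y11); H12 <- fill(adm$Y12)
  H21 <- fill(adm$Y21); H22 <- fill(adm$Y22)
  list(H11 = H11, H12 = H12, H21 = H21, H22 = H22,
       y11 = Re(stats::fft(H11, inverse = TRUE)) / n,
       y12 = Re(stats::fft(H12, inverse = TRUE)) / n,
       y21 = Re(stats::fft(H21, inverse = TRUE)) / n,
       y22 = Re(stats::fft(H22, inverse = TRUE)) / n)
}

#' Mean-pressure profile along a pure-alpha or pure-beta branch
#'
#' Given one period of pressure at the arterial and venous roots of a
#' tree pair, descends the selected branch accumulating the
#' frequency-domain state vessel by vessel and returns the cycle-mean
#' pressure at each vessel midpoint against radius, on both the arterial
#' and the mirrored venous side, together with the pressure at the
#' cutoff-level junction where the two sides meet.
#'
#' @param adm a [tree_admittance()].
#' @param p_a,p_v root pressure series over exactly one period (Pa).
#' @param path `"alpha"` (follow the larger daughter) or `"beta"`.
#' @return a data.frame (one row per generation along the path) with
#'   columns `gen`, `radius_cm`, `mean_p_art_mmHg`, `radius_v_cm`,
#'   `mean_p_ven_mmHg`; attributes `root_p_art_mmHg`, `root_p_ven_mmHg`,
#'   `cutoff_p_mmHg`, `drop_arterial_mmHg`, `drop_venous_mmHg`.
#' @export
branch_pressure_profile <- function(adm, p_a, p_v, path = c("alpha", "beta")) {
  path <- match.arg(path)
  stopifnot(inherits(adm, "tree_admittance"))
  spec <- adm$spec; fluid <- adm$fluid
  n <- length(p_a)
  ker <- admittance_kernel(adm, n)
  Pa <- stats::fft(p_a) / n; Pv <- stats::fft(p_v) / n
  K <- min(length(adm$omega) - 1L, floor((n - 1) / 2))
  idx <- 1:(K + 1)                       # harmonics 0..K
  Pa <- Pa[idx]; Pv <- Pv[idx]
  omega <- adm$omega[idx]
  Qa <- adm$Y11[idx] * Pa + adm$Y12[idx] * Pv
  Qv <- adm$Y21[idx] * Pa + adm$Y22[idx] * Pv
  occ <- function(a, b) spec$r_root_a * spec$alpha^a * spec$beta^b >= spec$r_min
  stepfun <- if (path == "alpha") function(a, b) c(a + 1, b) else function(a, b) c(a, b + 1)
  # state at the ports of the subtree rooted at (a, b)
  Sa <- list(P = Pa, Q = Qa); Sv <- list(P = Pv, Q = Qv)
  a <- 0; b <- 0
  gen <- 0; out <- NULL
  # cache of subtree two-ports (reuse the DP)
  tp_cache <- new.env(parent = emptyenv())
  subtree_tp <- function(a, b) {
    key <- paste0(a, ",", b)
    got <- tp_cache[[key]]
    if (is.null(got)) {
      sub <- spec
      sc <- spec$alpha^a * spec$beta^b
      sub$r_root_a <- spec$r_root_a * sc; sub$r_root_v <- spec$r_root_v * sc
      got <- .tree_two_port(sub, omega, fluid)
      tp_cache[[key]] <- got
    }
    got
  }
  inv_apply <- function(m, S)  # [p;q]_down = M^{-1} [p;q]_up (det = 1)
    list(P = m$D * S$P - m$B * S$Q, Q = -m$C * S$P + m$A * S$Q)
  fwd_apply <- function(m, S)  # [p;q]_up = M [p;q]_down
    list(P = m$A * S$P + m$B * S$Q, Q = m$C * S$P + m$D * S$Q)
  repeat {
    sc <- spec$alpha^a * spec$beta^b
    ra <- spec$r_root_a * sc; rv <- spec$r_root_v * sc
    Ma <- vessel_two_port(omega, ra, spec$lrr * ra, fluid)
    Mv <- vessel_two_port(omega, rv, spec$lrr * rv, fluid)
    Mah <- vessel_two_port(omega, ra, spec$lrr * ra / 2, fluid)
    Mvh <- vessel_two_port(omega, rv, spec$lrr * rv / 2, fluid)
    mid_a <- inv_apply(Mah, Sa)          # midpoint of arterial vessel
    S1 <- inv_apply(Ma, Sa)              # arterial junction below this vessel
    S2 <- fwd_apply(Mv, Sv)              # venous junction below this vessel
    mid_v <- fwd_apply(Mvh, Sv)          # midpoint of venous vessel
    out <- rbind(out, data.frame(
      gen = gen, radius_cm = ra,
      mean_p_art_mmHg = Pa_to_mmHg(Re(mid_a$P[1])),
      radius_v_cm = rv,
      mean_p_ven_mmHg = Pa_to_mmHg(Re(mid_v$P[1]))))
    nxt <- stepfun(a, b)
    if (!occ(nxt[1], nxt[2])) {
      term <- S1  # terminal junction: arterial and venous junctions coincide
      break
    }
    ch <- subtree_tp(nxt[1], nxt[2])
    q2 <- (S1$P - ch$A * S2$P) / ch$B    # flow at the child's venous port
    q1 <- ch$C * S2$P + ch$D * q2        # flow into the child's arterial port
    Sa <- list(P = S1$P, Q = q1)
    Sv <- list(P = S2$P, Q = q2)
    a <- nxt[1]; b <- nxt[2]; gen <- gen + 1
  }
  attr(out, "root_p_art_mmHg") <- Pa_to_mmHg(Re(Pa[1]))
  attr(out, "root_p_ven_mmHg") <- Pa_to_mmHg(Re(Pv[1]))
  attr(out, "cutoff_p_mmHg") <- Pa_to_mmHg(Re(term$P[1]))
  attr(out, "drop_arterial_mmHg") <- Pa_to_mmHg(Re(Pa[1]) - Re(term$P[1]))
  attr(out, "drop_venous_mmHg") <- Pa_to_mmHg(Re(term$P[1]) - Re(Pv[1]))
  out
}

#' Export tree cells as CSV / admittance as JSON
#'
#' @param tree a data.frame from [generate_tree()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_tree_csv <- function(tree, file) {
  utils::write.csv(tree[, c("a", "b", "multiplicity", "radius_cm",
                            "length_cm", "EhR0_mmHg")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_tree_csv
#' @param adm a [tree_admittance()].
#' @export
write_admittance_json <- function(adm, file) {
  as_pairs <- function(z) lapply(seq_along(z), function(i) c(Re(z[i]), Im(z[i])))
  obj <- list(period_s = adm$period, omega_rad_s = adm$omega,
              Y11 = as_pairs(adm$Y11), Y12 = as_pairs(adm$Y12),
              Y21 = as_pairs(adm$Y21), Y22 = as_pairs(adm$Y22))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
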