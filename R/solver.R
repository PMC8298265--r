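# Nonlinear 1D large-vessel solver: two-step (Richtmyer) Lax-Wendroff in
# conservation form with a geometric source for the taper and the
# flat-profile boundary-layer friction, closed at vessel ends by
# characteristic extrapolation combined with the boundary models (lumped
# inlet valve, loss-free bifurcations, structured-tree interfaces,
# prescribed outlet pressures).
#
# Riemann invariants of the system with the square-root tube law are
# W+- = u +- 4c, where c = sqrt(f / (2 rho)) (A/A0)^(1/4) and
# f = (4/3) Eh/R0.

#' Lumped pulmonary-valve parameters
#'
#' Pressure-flow relation dp = B q|q| / zeta^2 + L dq/dt across the
#' valve, with opening index zeta in `[0, 1]` driven by the pressure
#' difference (opening rate `k_open (1 - zeta) dp` for dp > 0, closing
#' rate `k_close zeta dp` for dp < 0).  Backflow is clamped to zero: the
#' valve does not allow regurgitation.
#'
#' @param annulus_area_cm2 effective annulus area (cm^2); default is the
#'   proximal cross-section of the main pulmonary artery.
#' @param cd discharge coefficient.
#' @param l_eff_cm effective inertial length (cm).
#' @param k_open,k_close opening/closing rate constants in 1/(Pa s).
#' @param rho blood density (kg/m^3).
#' @return list of valve constants (class `valve_params`).
#' @export
valve_params <- function(annulus_area_cm2 = pi * 1.55^2, cd = 0.95,
                         l_eff_cm = 0.25, k_open = 1, k_close = 1,
                         rho = 1e3) {
  A <- annulus_area_cm2 * 1e-4
  structure(list(
    B = rho / (2 * (cd * A)^2),
    L = rho * cm_to_m(l_eff_cm) / A,
    k_open = k_open, k_close = k_close, zeta_min = 1e-6),
    class = "valve_params")
}

# initial state: areas from a uniform pressure per vessel type (close to
# the control-case cycle means, which shortens the transient)
.init_state <- function(net, p_art = mmHg_to_Pa(16), p_vein = mmHg_to_Pa(5.2)) {
  p <- ifelse(net$vessels$type[rep(seq_len(nrow(net$vessels)),
                                   net$vessels$n)] == "vein", p_vein, p_art)
  s <- 1 + (p - net$p0) / net$f
  list(A = net$A0 * s^2, q = numeric(length(net$A0)))
}

# pressure on a node subset
.p_of <- function(net, A, idx = seq_along(A)) {
  net$p0 + net$f[idx] * (sqrt(A[idx] / net$A0[idx]) - 1)
}

#' Advance the network through cardiac cycles to a periodic state
#'
#' Core time-stepping driver used by [simulate_pulmonary()] and
#' [simulate_coupled()].  Runs whole cardiac cycles until the maximum
#' over vessels of the cycle-to-cycle relative L2 change of midpoint
#' pressure and flow falls below `tol`, or `cycles` is exhausted (then a
#' warning is issued and the last state returned).
#'
#' @param net a `pulmo_network` from [build_network()] or a toy fixture.
#' @param bc boundary-condition list.  `bc$inlet` is one of
#'   `list(type = "valve", p_fn =, valve = valve_params())`,
#'   `list(type = "q", fn =)` or `list(type = "p", fn =)`;
#'   `bc$outlet` is `list(type = "p", fn =)` where `fn(t)` returns one
#'   pressure (Pa) per free outlet (scalars are recycled).  Vessel ends
#'   listed in `net$interfaces` are closed by the structured trees
#'   instead and need no entry.
#' @param dt time step in s.
#' @param steps_per_cycle samples per cardiac cycle
#'   (period = `dt * steps_per_cycle`).
#' @param cycles maximum number of cycles.
#' @param tol cycle-to-cycle relative L2 convergence tolerance.
#' @param n_harmonics harmonics for the structured-tree admittance.
#' @param eps boundary-layer thickness in m; default
#'   [boundary_layer_thickness()] for this period.
#' @param la optional coupled left-atrium list (internal, built by
#'   [simulate_coupled()]).
#' @param init optional list with initial pressures `p_art`, `p_vein` (Pa).
#' @param trees optional precomputed list of [tree_admittance()] objects.
#' @param min_cycles run at least this many cycles before declaring
#'   convergence.
#' @return an object of class `pulmo_run`; see [simulate_pulmonary()].
#' @export
run_to_periodic <- function(net, bc, dt, steps_per_cycle, cycles = 10,
                            tol = 1e-3, n_harmonics = 512, eps = NULL,
                            la = NULL, init = list(), trees = NULL,
                            min_cycles = 2L, warm = NULL) {
  fluid <- net$fluid; rho <- fluid$rho; nu <- fluid$nu
  N <- as.integer(steps_per_cycle)
  period <- dt * N
  if (is.null(eps)) eps <- boundary_layer_thickness(period, fluid)
  nv <- nrow(net$vessels)
  A0 <- net$A0; f <- net$f; sf <- net$sf; p0 <- net$p0
  iL <- net$half$iL; iR <- net$half$iR
  A0h <- net$half$A0h; fh <- net$half$fh
  ii <- net$interior$ii; hl <- net$interior$hl; hr <- net$interior$hr
  rt_h <- dt / (2 * net$half$dxh)
  rt_i <- dt / net$interior$dxi
  fg_h <- fh / (3 * rho) * net$half$dA0dxh
  cfr <- 2 * pi * nu / eps
  f3r <- f / (3 * rho); f3rh <- fh / (3 * rho)
  # boundary bookkeeping
  i0v <- net$vessels$i0; i1v <- net$vessels$i1
  dx_v <- net$vessels$dx_m
  dx_of <- function(idx) dx_v[findInterval(idx, i0v)]
  jn <- net$junctions; ifc <- net$interfaces
  j_pe <- jn$p_end; j_d1 <- jn$d1_start; j_d2 <- jn$d2_start
  nj <- length(j_pe)
  a_end <- ifc$a_end; v_start <- ifc$v_start
  n_ifc <- length(a_end)
  free_out <- setdiff(i1v, c(j_pe, a_end))
  free_in <- setdiff(i0v, c(j_d1, j_d2, v_start))
  if (length(free_in) != 1L) stop("network must have exactly one inlet")
  inlet <- free_in
  n_out <- length(free_out)
  dx_in <- dx_of(inlet); dx_out <- dx_of(free_out)
  if (nj) { dx_pe <- dx_of(j_pe); dx_d1 <- dx_of(j_d1); dx_d2 <- dx_of(j_d2) }
  if (n_ifc) { dx_ae <- dx_of(a_end); dx_vs <- dx_of(v_start) }
  cfl_dx <- dx_v[findInterval(seq_along(A0), i0v)]
  # structured-tree kernels
  if (n_ifc > 0) {
    if (is.null(trees)) {
      trees <- lapply(seq_len(n_ifc), function(k) {
        sp <- tree_spec(ifc$r_root_a[k], ifc$r_root_v[k],
                        alpha = net$tree$alpha, beta = net$tree$beta,
                        r_min = net$tree$r_min, lrr = net$tree$lrr)
        tree_admittance(sp, period, n_harmonics, fluid)
      })
    }
    # Lift the high-frequency (characteristic) input admittance of each
    # tree root out of the convolution and apply it instantaneously:
    # Y11 -> ga + [Y11 - ga], Y22 -> -gv + [Y22 + gv].  The harmonics up
    # to n_harmonics are reproduced exactly; frequencies beyond the
    # truncation see the physical characteristic admittance instead of
    # an open circuit, which keeps the interface wave-absorbing.
    g_inf <- function(r_cm) {
      r <- cm_to_m(r_cm); A0r <- pi * r^2
      Cr <- 3 * A0r / (2 * mmHg_to_Pa(small_vessel_stiffness(r_cm)))
      sqrt(Cr * A0r / fluid$rho)
    }
    ga_inf <- vapply(seq_len(n_ifc), function(k) g_inf(trees[[k]]$spec$r_root_a),
                     numeric(1))
    gv_inf <- vapply(seq_len(n_ifc), function(k) g_inf(trees[[k]]$spec$r_root_v),
                     numeric(1))
    kers <- lapply(seq_len(n_ifc), function(k) {
      am <- trees[[k]]
      am$Y11 <- am$Y11 - ga_inf[k]
      am$Y22 <- am$Y22 + gv_inf[k]
      admittance_kernel(am, n = N)
    })
    y011 <- ga_inf + vapply(kers, function(k) k$y11[1], numeric(1))
    y012 <- vapply(kers, function(k) k$y12[1], numeric(1))
    y021 <- vapply(kers, function(k) k$y21[1], numeric(1))
    y022 <- -gv_inf + vapply(kers, function(k) k$y22[1], numeric(1))
    # reversed history kernels, stacked for one BLAS product per buffer:
    # columns (k) then (k + n_ifc) hold the kernels against the arterial
    # and venous history respectively for output row k
    Ya_ker <- cbind(vapply(kers, function(k) rev(k$y11[2:N]), numeric(N - 1)),
                    vapply(kers, function(k) rev(k$y21[2:N]), numeric(N - 1)))
    Yv_ker <- cbind(vapply(kers, function(k) rev(k$y12[2:N]), numeric(N - 1)),
                    vapply(kers, function(k) rev(k$y22[2:N]), numeric(N - 1)))
    dsel <- cbind(seq_len(n_ifc), seq_len(n_ifc))          # diag picks
    dsel2 <- cbind(seq_len(n_ifc), n_ifc + seq_len(n_ifc))
  }
  # state (fresh, or continued from a previous run of the same layout)
  if (!is.null(warm)) {
    A <- warm$A; q <- warm$q; zeta <- warm$zeta; q_valve <- warm$q_valve
    if (n_ifc > 0) { Pa_buf <- warm$Pa_buf; Pv_buf <- warm$Pv_buf }
  } else {
    st <- do.call(.init_state, c(list(net), init))
    A <- st$A; q <- st$q
    zeta <- 0; q_valve <- 0
    if (n_ifc > 0) {
      Pa_buf <- matrix(rep(.p_of(net, A, a_end), each = 2 * N), 2 * N, n_ifc)
      Pv_buf <- matrix(rep(.p_of(net, A, v_start), each = 2 * N), 2 * N, n_ifc)
    }
  }
  gstep <- 0L
  vl <- bc$inlet$valve
  # recording
  mid <- net$midpoints
  cur_p <- matrix(0, N, nv); cur_q <- matrix(0, N, nv); cur_A <- matrix(0, N, nv)
  prev_p <- NULL; prev_q <- NULL
  if (n_ifc) {
    rec_pa <- matrix(0, N, n_ifc); rec_pv <- matrix(0, N, n_ifc)
    rec_qa <- matrix(0, N, n_ifc); rec_qv <- matrix(0, N, n_ifc)
  }
  rec_qout <- matrix(0, N, n_out); rec_pout <- matrix(0, N, n_out)
  rec_qin <- numeric(N); rec_zeta <- numeric(N); rec_pin <- numeric(N)
  la_state <- la$state; q_la <- la$q_la; q_pc_prev <- la$q_pc_prev
  if (!is.null(la)) {
    rec_V <- numeric(N); rec_pla <- numeric(N); rec_qmv <- numeric(N)
    rec_qla <- matrix(0, N, n_out); rec_th <- numeric(N)
  }
  conv <- NULL; converged <- FALSE
  max_jres <- 0; newton_fail <- FALSE
  time0 <- 0
  for (cyc in seq_len(cycles)) {
    for (s in seq_len(N)) {
      gstep <- gstep + 1L
      tn <- (gstep - 1L) * dt; tnp <- gstep * dt
      # coupled chamber: relax the interface flow (Eq. of the scheme),
      # advance the 0D atrium, then hand its pressure to the vein outlets
      if (!is.null(la)) {
        q_pc <- q[free_out]
        th <- if (abs(la_state$dpdt) > la$theta_trigger) la$theta_reduced
              else la$theta_default
        q_la <- q_la + th[1] * (q_pc - q_la) + th[2] * (q_pc - q_pc_prev)
        q_pc_prev <- q_pc
        la_state <- .la_advance(la_state, sum(q_la), tn, dt, la)
        p_out_val <- rep(la_state$p_la, n_out)
      } else {
        p_out_val <- bc$outlet$fn(tnp)
        if (length(p_out_val) == 1L) p_out_val <- rep(p_out_val, n_out)
      }
      # ---- interior Lax-Wendroff step ----
      Bq <- f3r * A * sqrt(A / A0)
      Sf <- -cfr * q / sqrt(pi * A)
      F2 <- q * q / A + Bq
      Ahf <- 0.5 * (A[iL] + A[iR]) - rt_h * (q[iR] - q[iL])
      qhf <- 0.5 * (q[iL] + q[iR]) - rt_h * (F2[iR] - F2[iL]) +
        (dt / 4) * (Sf[iL] + Sf[iR])
      if (any(Ahf <= 0))
        stop("negative area in half step (cycle ", cyc, ", step ", s, ")")
      rat <- Ahf / A0h
      F2h <- qhf * qhf / Ahf + f3rh * Ahf * sqrt(rat)
      S2h <- fg_h * rat * sqrt(rat) - cfr * qhf / sqrt(pi * Ahf)
      Anew <- A; qnew <- q
      Anew[ii] <- A[ii] - rt_i * (qhf[hr] - qhf[hl])
      qnew[ii] <- q[ii] - rt_i * (F2h[hr] - F2h[hl]) +
        (dt / 2) * (S2h[hr] + S2h[hl])
      # ---- characteristic fields at old time ----
      cb <- sf * (A / A0)^0.25     # wave speed everywhere (also CFL guard)
      ub <- q / A
      if (s %% 64L == 1L) {
        if (max((abs(ub) + cb) * dt / cfl_dx) > 1)
          stop("CFL violated (cycle ", cyc, ", step ", s, "): reduce dt")
        prange <- range(.p_of(net, A))
        if (prange[1] < mmHg_to_Pa(-20) || prange[2] > mmHg_to_Pa(200))
          stop("pressure out of physiological bounds (",
               round(Pa_to_mmHg(prange[1]), 1), ", ",
               round(Pa_to_mmHg(prange[2]), 1), ") mmHg")
      }
      Wfwd <- ub + 4 * cb; Wbwd <- ub - 4 * cb
      extrap_fwd <- function(idx, dx) {   # distal ends, lambda+ outgoing
        thx <- pmin(pmax((ub[idx] + cb[idx]) * dt / dx, 0), 1)
        Wfwd[idx] - thx * (Wfwd[idx] - Wfwd[idx - 1L])
      }
      extrap_bwd <- function(idx, dx) {   # proximal ends, lambda- outgoing
        thx <- pmin(pmax((cb[idx] - ub[idx]) * dt / dx, 0), 1)
        Wbwd[idx] + thx * (Wbwd[idx + 1L] - Wbwd[idx])
      }
      # ---- inlet ----
      Wm <- extrap_bwd(inlet, dx_in)
      itype <- bc$inlet$type
      if (itype == "valve") {
        p_up <- bc$inlet$p_fn(tn)
        p_in <- .p_of(net, A, inlet)
        dp <- p_up - p_in
        dz <- if (dp > 0) vl$k_open * (1 - zeta) * dp else vl$k_close * zeta * dp
        zeta <- min(max(zeta + dt * dz, 0), 1)
        if (zeta <= vl$zeta_min) {
          q_valve <- 0
        } else {
          q_valve <- (q_valve + dt * dp / vl$L) /
            (1 + dt * vl$B * abs(q_valve) / (zeta^2 * vl$L))
          if (q_valve < 0) q_valve <- 0
        }
        qb <- q_valve
        rec_pin[s] <- p_up
      } else if (itype == "q") {
        qb <- bc$inlet$fn(tnp)
      } else qb <- NULL
      if (!is.null(qb)) {      # solve u - 4c = Wm with u = qb/A
        An <- A[inlet]
        for (it in 1:50) {
          cA <- sf[inlet] * (An / A0[inlet])^0.25
          Fv <- qb / An - 4 * cA - Wm
          dA_ <- Fv / (-qb / An^2 - cA / An)
          An <- An - dA_
          if (An <= 0) An <- 0.5 * A0[inlet]
          if (abs(dA_) < 1e-12 * A0[inlet]) break
        }
        Anew[inlet] <- An; qnew[inlet] <- qb
      } else {                 # prescribed inlet pressure
        An <- tube_law_area(bc$inlet$fn(tnp),
                            list(A0 = A0[inlet], f = f[inlet], p0 = p0))
        cA <- sf[inlet] * (An / A0[inlet])^0.25
        Anew[inlet] <- An
        qnew[inlet] <- An * (Wm + 4 * cA)
      }
      rec_qin[s] <- qnew[inlet]; rec_zeta[s] <- zeta
      # ---- junctions: continuity of static pressure + mass ----
      if (nj) {
        Wp <- extrap_fwd(j_pe, dx_pe)
        W1 <- extrap_bwd(j_d1, dx_d1)
        W2 <- extrap_bwd(j_d2, dx_d2)
        pj <- .p_of(net, A, j_pe)
        for (it in 1:50) {
          sp_p <- pmax(1 + (pj - p0) / f[j_pe], 1e-6)
          sp_1 <- pmax(1 + (pj - p0) / f[j_d1], 1e-6)
          sp_2 <- pmax(1 + (pj - p0) / f[j_d2], 1e-6)
          Ap <- A0[j_pe] * sp_p^2; A1 <- A0[j_d1] * sp_1^2; A2 <- A0[j_d2] * sp_2^2
          cp <- sf[j_pe] * sqrt(sp_p); c1 <- sf[j_d1] * sqrt(sp_1)
          c2 <- sf[j_d2] * sqrt(sp_2)
          up <- Wp - 4 * cp; u1 <- W1 + 4 * c1; u2 <- W2 + 4 * c2
          Fj <- Ap * up - A1 * u1 - A2 * u2
          dFj <- (2 * A0[j_pe] * sp_p / f[j_pe]) * up - Ap * 2 * cp / (sp_p * f[j_pe]) -
                 (2 * A0[j_d1] * sp_1 / f[j_d1]) * u1 - A1 * 2 * c1 / (sp_1 * f[j_d1]) -
                 (2 * A0[j_d2] * sp_2 / f[j_d2]) * u2 - A2 * 2 * c2 / (sp_2 * f[j_d2])
          dpj <- Fj / dFj
          pj <- pj - dpj
          if (max(abs(dpj)) < 1e-9) break
        }
        if (it == 50 && max(abs(dpj)) > 1e-6) newton_fail <- TRUE
        max_jres <- max(max_jres, max(abs(Fj)))
        Anew[j_pe] <- Ap; qnew[j_pe] <- Ap * up
        Anew[j_d1] <- A1; qnew[j_d1] <- A1 * u1
        Anew[j_d2] <- A2; qnew[j_d2] <- A2 * u2
      }
      # ---- structured-tree interfaces ----
      if (n_ifc) {
        sti <- (gstep %% N) + 1L
        sl <- sti:(sti + N - 2L)
        Ga <- crossprod(Pa_buf[sl, , drop = FALSE], Ya_ker)  # n_ifc x 2n_ifc
        Gv <- crossprod(Pv_buf[sl, , drop = FALSE], Yv_ker)
        Ha <- Ga[dsel] + Gv[dsel]
        Hv <- Ga[dsel2] + Gv[dsel2]
        Wa <- extrap_fwd(a_end, dx_ae)
        Wv <- extrap_bwd(v_start, dx_vs)
        pa <- .p_of(net, A, a_end); pv <- .p_of(net, A, v_start)
        for (it in 1:50) {
          spa <- pmax(1 + (pa - p0) / f[a_end], 1e-6)
          spv <- pmax(1 + (pv - p0) / f[v_start], 1e-6)
          Aa <- A0[a_end] * spa^2; Av <- A0[v_start] * spv^2
          ca <- sf[a_end] * sqrt(spa); cv <- sf[v_start] * sqrt(spv)
          ua <- Wa - 4 * ca; uv <- Wv + 4 * cv
          qa <- y011 * pa + y012 * pv + Ha
          qv <- y021 * pa + y022 * pv + Hv
          F1 <- qa - Aa * ua
          F2v <- qv - Av * uv
          J11 <- y011 - ((2 * A0[a_end] * spa / f[a_end]) * ua -
                         Aa * 2 * ca / (spa * f[a_end]))
          J22 <- y022 - ((2 * A0[v_start] * spv / f[v_start]) * uv +
                         Av * 2 * cv / (spv * f[v_start]))
          detJ <- J11 * J22 - y012 * y021
          dpa <- (F1 * J22 - F2v * y012) / detJ
          dpv <- (J11 * F2v - y021 * F1) / detJ
          pa <- pa - dpa; pv <- pv - dpv
          if (max(abs(dpa), abs(dpv)) < 1e-9) break
        }
        if (it == 50 && max(abs(dpa), abs(dpv)) > 1e-6) newton_fail <- TRUE
        spa <- pmax(1 + (pa - p0) / f[a_end], 1e-6)
        spv <- pmax(1 + (pv - p0) / f[v_start], 1e-6)
        Aa <- A0[a_end] * spa^2; Av <- A0[v_start] * spv^2
        qa <- y011 * pa + y012 * pv + Ha
        qv <- y021 * pa + y022 * pv + Hv
        Anew[a_end] <- Aa; qnew[a_end] <- qa
        Anew[v_start] <- Av; qnew[v_start] <- qv
        posb <- ((gstep - 1L) %% N) + 1L
        Pa_buf[posb, ] <- pa; Pa_buf[posb + N, ] <- pa
        Pv_buf[posb, ] <- pv; Pv_buf[posb + N, ] <- pv
        rec_pa[s, ] <- pa; rec_pv[s, ] <- pv
        rec_qa[s, ] <- qa; rec_qv[s, ] <- qv
      }
      # ---- free outlets: prescribed pressure ----
      if (n_out) {
        spo <- pmax(1 + (p_out_val - p0) / f[free_out], 1e-6)
        Ao <- A0[free_out] * spo^2
        co <- sf[free_out] * sqrt(spo)
        Wo <- extrap_fwd(free_out, dx_out)
        Anew[free_out] <- Ao
        qnew[free_out] <- Ao * (Wo - 4 * co)
        rec_qout[s, ] <- qnew[free_out]; rec_pout[s, ] <- p_out_val
      }
      A <- Anew; q <- qnew
      if (!is.null(la)) {
        rec_V[s] <- la_state$V; rec_pla[s] <- la_state$p_la
        rec_qmv[s] <- la_state$q_mv; rec_qla[s, ] <- q_la
        rec_th[s] <- th[1]
      }
      cur_p[s, ] <- .p_of(net, A, mid)
      cur_q[s, ] <- q[mid]
      cur_A[s, ] <- A[mid]
    }
    # cycle-to-cycle convergence
    if (!is.null(prev_p)) {
      relL2 <- function(x, y) sqrt(colSums((x - y)^2) / pmax(colSums(y^2), 1e-300))
      metric <- max(relL2(cur_p, prev_p), relL2(cur_q, prev_q))
      conv <- rbind(conv, data.frame(cycle = cyc, metric = metric))
      if (metric < tol && cyc >= min_cycles) { converged <- TRUE }
      if (!is.null(la) && nrow(conv) >= 3) {
        m <- utils::tail(conv$metric, 3)
        if (m[3] > 10 * m[1] && m[3] > 1)
          stop("interface oscillation growing over two cycles; ",
               "reduce the relaxation parameters theta")
      }
    }
    if (converged) break
    prev_p <- cur_p; prev_q <- cur_q
  }
  if (!converged && cycles > min_cycles)
    warning("run did not reach tol = ", tol, "; last metric = ",
            signif(utils::tail(conv$metric, 1), 3))
  if (newton_fail) warning("boundary Newton iterations hit the cap at least once")
  t_cyc <- (seq_len(N) - 1L) * dt
  out <- list(
    time = t_cyc, dt = dt, period = period, steps_per_cycle = N,
    cycles_run = cyc, converged = converged, convergence = conv,
    vessels = net$vessels$name,
    probe_p = cur_p, probe_q = cur_q, probe_A = cur_A,
    q_inlet = rec_qin, zeta = rec_zeta, p_upstream = rec_pin,
    q_outlet = rec_qout, p_outlet = rec_pout,
    net = net, trees = if (n_ifc) trees else NULL, eps = eps,
    junction_residual_max = max_jres,
    state = list(A = A, q = q, zeta = zeta, q_valve = q_valve,
                 Pa_buf = if (n_ifc) Pa_buf, Pv_buf = if (n_ifc) Pv_buf)
  )
  if (n_ifc) {
    colnames(rec_pa) <- colnames(rec_pv) <- colnames(rec_qa) <-
      colnames(rec_qv) <- ifc$artery
    out$interface <- list(p_a = rec_pa, p_v = rec_pv, q_a = rec_qa, q_v = rec_qv,
                          artery = ifc$artery, vein = ifc$vein)
  }
  if (!is.null(la)) {
    out$la <- list(V = rec_V, p_la = rec_pla, q_mv = rec_qmv,
                   q_la = rec_qla, theta1 = rec_th, pars = la$pars)
    out$la_final <- list(state = la_state, q_la = q_la, q_pc_prev = q_pc_prev)
  }
  class(out) <- "pulmo_run"
  out
}

#' Stand-alone pulmonary circulation simulation
#'
#' Runs the 1D pulmonary network under a right-ventricular pressure
#' waveform (through the lumped pulmonary valve) at the inlet and a
#' prescribed typical left-atrial pressure at the four vein outlets,
#' cycling to a periodic state.  This is the configuration used to
#' initialise the coupled model, and also a complete simulation in its
#' own right.
#'
#' @param net a `pulmo_network` from [build_network()].
#' @param case a [case_config()]; sets the period and the RV waveform
#'   anchors.
#' @param steps_per_cycle samples per cycle (default 2^14, giving the
#'   reference time step of about 4.9e-5 s at T = 0.8 s).
#' @param cycles maximum cycles (default 10).
#' @param tol convergence tolerance on the cycle-to-cycle relative L2
#'   change (default 1e-3).
#' @param la_pressure optional function of time (Pa) for the vein
#'   outlets; default is the typical left-atrial waveform
#'   ([la_pressure_waveform()]) at this period.
#' @param valve a [valve_params()].
#' @param n_harmonics structured-tree harmonics (default 512).
#' @param ... further arguments passed to [run_to_periodic()].
#' @return a `pulmo_run` with per-cycle midpoint pressure/flow/area
#'   series, interface and valve records, and the tree admittances.
#' @export
simulate_pulmonary <- function(net, case = case_config("control"),
                               steps_per_cycle = 16384L, cycles = 10,
                               tol = 1e-3, la_pressure = NULL,
                               valve = valve_params(), n_harmonics = 512,
                               ...) {
  period <- case$period
  dt <- period / steps_per_cycle
  rv <- rv_pressure_waveform(period = period, systolic = case$rv_systolic,
                             systole = case$systole)
  if (is.null(la_pressure))
    la_pressure <- la_pressure_waveform(period = period)
  bc <- list(inlet = list(type = "valve", p_fn = rv, valve = valve),
             outlet = list(type = "p", fn = la_pressure))
  run <- run_to_periodic(net, bc, dt = dt, steps_per_cycle = steps_per_cycle,
                         cycles = cycles, tol = tol,
                         n_harmonics = n_harmonics, ...)
  run$case <- case
  run
}

#' @export
print.pulmo_run <- function(x, ...) {
  cat("pulmo_run:", length(x$vessels), "vessels, ", x$cycles_run,
      "cycles of", x$period, "s (dt =", signif(x$dt, 3), "s)\n")
  cat(" converged:", x$converged)
  if (!is.null(x$convergence) && nrow(x$convergence))
    cat(" (last cycle-to-cycle metric ",
        signif(utils::tail(x$convergence$metric, 1), 3), ")", sep = "")
  cat("\n")
  im <- match("MPA", x$vessels)
  if (!is.na(im)) {
    p <- Pa_to_mmHg(x$probe_p[, im])
    cat(sprintf(" MPA midpoint pressure: %.1f / %.1f mmHg (sys/dia)\n",
                max(p), min(p)))
  }
  invisible(x)
}
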