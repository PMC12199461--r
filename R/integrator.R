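# Variable-cell MTMD integrator: generalized Stoermer-Verlet (leapfrog) for
# the Hamiltonian
#   H = 1/2 ps^T G^-1 ps + 1/(2W) Tr(ph^T ph) + U(s,h) + P det h,
# with G = H^T M(x) H the mass-weighted metric tensor.  The first momentum
# half-kick is implicit in ps (fixed-point iteration); the position update
# is implicit in s (one fixed-point step, then Newton-Raphson).  Exactly one
# force evaluation per step; mass-matrix evaluations at the advanced
# positions are reused by the next step.

#' Integrator configuration
#'
#' @param dt Time step in fs.
#' @param W Fictitious cell mass (u).
#' @param P External pressure in GPa (converted to eV/A^3 internally).
#' @param uniform_scaling Restrict cell dynamics to uniform scalings by
#'   projecting the cell-momentum updates onto `span(h)`.
#' @param fix_cell Freeze the cell entirely (constant-volume dynamics).
#' @param fp_tol Convergence tolerance (max-norm change per iterate) of the
#'   fixed-point solve for the momentum half-kick.
#' @param fp_max_iter Iteration cap for the fixed-point solve (default 30).
#' @param newton_tol Residual tolerance (max-norm) of the position solve.
#' @param newton_max_iter Iteration cap for the Newton solve (default 10).
#' @return Object of class `integrator_config`.
#' @export
integrator_config <- function(dt, W = 20, P = 1e-4, uniform_scaling = TRUE,
                              fix_cell = FALSE, fp_tol = 1e-12,
                              fp_max_iter = 30, newton_tol = 1e-12,
                              newton_max_iter = 10) {
  stopifnot(dt > 0, W > 0, fp_tol > 0, newton_tol > 0)
  structure(list(dt = dt, dt_int = .fs_to_internal(dt), W = W,
                 P = P * .GPA, P_GPa = P,
                 uniform_scaling = uniform_scaling, fix_cell = fix_cell,
                 fp_tol = fp_tol, fp_max_iter = fp_max_iter,
                 newton_tol = newton_tol, newton_max_iter = newton_max_iter),
            class = "integrator_config")
}

#' Project a cell-momentum increment onto uniform scalings
#'
#' Orthogonal projection (Frobenius inner product) of a 3 x 3 increment
#' onto the one-dimensional subspace spanned by the current cell matrix,
#' so that only uniform rescalings of the cell are driven.
#'
#' @param increment 3 x 3 matrix.
#' @param h Current cell matrix.
#' @return Projected 3 x 3 matrix.
#' @export
project_uniform_scaling <- function(increment, h) {
  if (abs(det(h)) < 1e-14) stop("cell matrix must be invertible")
  hn <- h / sqrt(sum(h * h))
  sum(increment * hn) * hn
}

# --- kinetic-term machinery (block representation) -------------------------

# y = H^-T ps per atom; Z = M^-1 y in block layout; KE; sdot = G^-1 ps
.kin_setup <- function(me, h, ps) {
  hin <- solve(h)
  y <- t(hin) %*% ps                  # h^-T ps_i per atom
  Y <- .gather(y, me$idx)
  Z <- block_apply_cpp(me$Ainv, Y) / me$c
  zfull <- .scatter(Z, me$idx, me$n3)
  list(hin = hin, y = y, Y = Y, Z = Z, zfull = zfull,
       KE = 0.5 * sum(Y * Z), w = hin %*% zfull)
}

# kinetic contributions to the momentum equations:
# fs_i = -1/2 ps^T dG^-1/ds_i ps   (3 x N, in fractional coordinates)
# fh   = -1/2 ps^T dG^-1/dh ps     (3 x 3)
.kin_forces <- function(me, h, kin, s, want_h = TRUE) {
  n <- me$n3 / 3
  if (is.null(me$dA)) {
    fs <- matrix(0, 3, n)
    fh <- if (want_h) kin$y %*% t(kin$w) else NULL
    return(list(fs = fs, fh = fh))
  }
  Q <- block_quad_cpp(me$dA, kin$Z)
  dcdx <- -(me$c / me$n3) * me$Tr
  fx <- 0.5 * (me$c * Q + (2 * kin$KE / me$c) * dcdx)
  fxfull <- .scatter(fx, me$idx, me$n3)
  fs <- crossprod(h, fxfull)
  fh <- NULL
  if (want_h) {
    fh <- kin$y %*% t(kin$w) + fxfull %*% t(s)
  }
  list(fs = fs, fh = fh)
}

# pressure + potential part of the ph equation of motion
.cell_force_static <- function(ffres, h, cfg) {
  -ffres$dU_dh - cfg$P * det(h) * t(solve(h))
}

# --- sub-steps -------------------------------------------------------------

# first momentum half-kick: implicit in ps (fixed-point), then explicit ph
.momentum_half <- function(state, me, ffres, cfg) {
  dt2 <- cfg$dt_int / 2
  ps0 <- state$ps
  if (is.null(me$dA)) {
    ps_half <- ps0 - dt2 * ffres$dU_ds
    iters <- 1L
  } else {
    psk <- ps0
    iters <- 0L
    history <- numeric(0)
    tol <- cfg$fp_tol * max(1, max(abs(ps0)))   # relative to momentum scale
    repeat {
      iters <- iters + 1L
      kin <- .kin_setup(me, state$h, psk)
      f <- .kin_forces(me, state$h, kin, state$s, want_h = FALSE)$fs
      psn <- ps0 + dt2 * (f - ffres$dU_ds)
      delta <- max(abs(psn - psk))
      history <- c(history, delta)
      psk <- psn
      if (delta < tol) break
      if (iters >= cfg$fp_max_iter)
        stop(sprintf(paste0("momentum half-kick fixed point did not converge",
                            " in %d iterations (last updates: %s); reduce the",
                            " time step"),
                     iters,
                     paste(signif(utils::tail(history, 4), 3),
                           collapse = ", ")))
    }
    ps_half <- psk
  }
  ph_half <- state$ph
  if (!cfg$fix_cell) {
    kin <- .kin_setup(me, state$h, ps_half)
    fh <- .kin_forces(me, state$h, kin, state$s, want_h = TRUE)$fh
    inc <- fh + .cell_force_static(ffres, state$h, cfg)
    if (cfg$uniform_scaling) inc <- project_uniform_scaling(inc, state$h)
    ph_half <- state$ph + dt2 * inc
  }
  list(ps_half = ps_half, ph_half = ph_half, fp_iters = iters)
}

# position update: h explicit, s implicit (fixed point + Newton-Raphson)
.position_full <- function(state, ps_half, ph_half, model, top, cfg, me_old) {
  dt <- cfg$dt_int
  dt2 <- dt / 2
  h1 <- if (cfg$fix_cell) state$h else state$h + dt * ph_half / cfg$W
  if (det(h1) <= 0) stop("cell inverted during position update")
  kin0 <- .kin_setup(me_old, state$h, ps_half)
  v0 <- kin0$w

  if (is.null(me_old$dA)) {
    # constant mass matrix: G^-1 depends only on h, update is explicit
    kin1 <- .kin_setup(me_old, h1, ps_half)
    s1 <- state$s + dt2 * (v0 + kin1$w)
    return(list(s = s1, h = h1, newton_iters = 1L, me = me_old))
  }

  s1 <- state$s
  me <- NULL
  # one fixed-point step from the current position
  me <- mass_eval(model, h1 %*% s1, top, deriv = TRUE)
  kin <- .kin_setup(me, h1, ps_half)
  s1 <- state$s + dt2 * (v0 + kin$w)
  iters <- 1L
  hin1 <- solve(h1)
  repeat {
    iters <- iters + 1L
    me <- mass_eval(model, h1 %*% s1, top, deriv = TRUE)
    kin <- .kin_setup(me, h1, ps_half)
    Fres <- s1 - state$s - dt2 * (v0 + kin$w)
    if (max(abs(Fres)) < cfg$newton_tol) break
    if (iters > cfg$newton_max_iter)
      stop(paste0("position update Newton iteration did not converge; ",
                  "reduce the time step"))
    step_ok <- tryCatch({
      K <- block_jac_cpp(me$dA, me$Ainv, kin$Z)
      Jb <- block_sandwich_cpp(K, hin1, h1)       # block part (x -> s chain)
      D <- Jb * dt2
      for (b in seq_len(me$nb)) D[, , b] <- D[, , b] + diag(me$d)
      u <- kin$w                                   # H^-1 Z (3 x N)
      Trfull <- .scatter(me$Tr, me$idx, me$n3)
      v <- -(1 / me$n3) * crossprod(h1, Trfull)    # dc/ds / c
      rhsb <- .gather(-Fres, me$idx)
      ub <- .gather(u, me$idx)
      a1 <- cube_solve_cpp(D, rhsb)
      a2 <- cube_solve_cpp(D, ub)
      vf <- as.numeric(v)
      num <- sum(vf * .scatter(a1, me$idx, me$n3))
      den <- 1 + dt2 * sum(vf * .scatter(a2, me$idx, me$n3))
      delta_b <- a1 - (dt2 * num / den) * a2
      .scatter(delta_b, me$idx, me$n3)
    }, error = function(e) NULL)
    if (is.null(step_ok)) {
      # damped fixed point fallback
      s_fp <- state$s + dt2 * (v0 + kin$w)
      s1 <- s1 + 0.5 * (s_fp - s1)
    } else {
      s1 <- s1 + step_ok
    }
  }
  list(s = s1, h = h1, newton_iters = iters, me = me)
}

# final momentum half-kick, explicit at the advanced positions
.momentum_final <- function(s1, h1, ps_half, ph_half, me1, ffres1, cfg) {
  dt2 <- cfg$dt_int / 2
  kin <- .kin_setup(me1, h1, ps_half)
  f <- .kin_forces(me1, h1, kin, s1, want_h = !cfg$fix_cell)
  ps1 <- ps_half + dt2 * (f$fs - ffres1$dU_ds)
  ph1 <- ph_half
  if (!cfg$fix_cell) {
    inc <- f$fh + .cell_force_static(ffres1, h1, cfg)
    if (cfg$uniform_scaling) inc <- project_uniform_scaling(inc, h1)
    ph1 <- ph_half + dt2 * inc
  }
  list(ps = ps1, ph = ph1)
}

# --- public sub-step wrappers ---------------------------------------------

#' First (implicit) momentum half-step
#'
#' Solves the implicit half-kick for the scaled momenta by fixed-point
#' iteration, then updates the cell momenta explicitly; with the
#' uniform-scaling constraint the cell increment is projected first.
#'
#' @param state An [system_state()].
#' @param model A mass model.
#' @param ff A force field.
#' @param top An [topology()].
#' @param cfg An [integrator_config()].
#' @return List with `ps_half`, `ph_half` and `fp_iters`.
#' @export
momentum_half_step <- function(state, model, ff, top, cfg) {
  me <- mass_eval(model, positions(state), top, deriv = TRUE)
  ffres <- energy_forces(ff, state, top)
  .momentum_half(state, me, ffres, cfg)
}

#' Full (implicit) position step
#'
#' Advances the cell explicitly from the half-step cell momenta, then
#' solves the implicit position update (the inverse metric tensor is
#' re-evaluated at the trial positions) with one fixed-point step followed
#' by Newton-Raphson.
#'
#' @inheritParams momentum_half_step
#' @param ps_half,ph_half Half-step momenta.
#' @return List with `s`, `h` and `newton_iters`.
#' @export
position_full_step <- function(state, ps_half, ph_half, model, top, cfg) {
  me <- mass_eval(model, positions(state), top, deriv = TRUE)
  res <- .position_full(state, ps_half, ph_half, model, top, cfg, me)
  res[c("s", "h", "newton_iters")]
}

#' Final (explicit) momentum half-step
#'
#' @inheritParams position_full_step
#' @param state_new State holding the advanced positions (momenta ignored).
#' @return List with `ps` and `ph`.
#' @export
momentum_final_half_step <- function(state_new, ps_half, ph_half, model, ff,
                                     top, cfg) {
  me1 <- mass_eval(model, positions(state_new), top, deriv = TRUE)
  ffres1 <- energy_forces(ff, state_new, top)
  .momentum_final(state_new$s, state_new$h, ps_half, ph_half, me1, ffres1, cfg)
}

#' One step of the symplectic MTMD integrator
#'
#' Composition of the implicit momentum half-kick, the implicit position
#' update and the explicit final half-kick.  Exactly one force evaluation
#' per step (at the advanced positions); pass `cache` from the previous
#' step to reuse it.
#'
#' @inheritParams momentum_half_step
#' @param cache Optional list `(me, ff)` of evaluations at `state` as
#'   returned in the `cache` element of a previous step.
#' @return List with `state` (advanced [system_state()]), `cache`, and
#'   diagnostics `fp_iters`, `newton_iters`, `c_q`, `U`.
#' @export
step_mtmd <- function(state, model, ff, top, cfg, cache = NULL) {
  if (is.null(cache)) {
    cache <- list(me = mass_eval(model, positions(state), top, deriv = TRUE),
                  ff = energy_forces(ff, state, top))
  }
  mh <- .momentum_half(state, cache$me, cache$ff, cfg)
  pf <- .position_full(state, mh$ps_half, mh$ph_half, model, top, cfg,
                       cache$me)
  me1 <- mass_eval(model, pf$h %*% pf$s, top, deriv = TRUE)
  st_new <- system_state(pf$s, pf$h, state$ps, state$ph,
                         t = state$t + cfg$dt)
  ffres1 <- energy_forces(ff, st_new, top)
  mf <- .momentum_final(pf$s, pf$h, mh$ps_half, mh$ph_half, me1, ffres1, cfg)
  st_new$ps <- mf$ps
  st_new$ph <- mf$ph
  list(state = st_new, cache = list(me = me1, ff = ffres1),
       fp_iters = mh$fp_iters, newton_iters = pf$newton_iters,
       c_q = me1$c, U = ffres1$U)
}

#' Conserved quantity (enthalpy-like) of the MTMD Hamiltonian
#'
#' Evaluates \eqn{\tfrac12 p_s^T G^{-1} p_s + \mathrm{Tr}(p_h^T p_h)/(2W) +
#' U + P \det h} (eV).  With a frozen cell the two cell terms are dropped.
#'
#' @inheritParams momentum_half_step
#' @return Scalar energy in eV.
#' @export
conserved_quantity <- function(state, model, ff, top, cfg) {
  me <- mass_eval(model, positions(state), top, deriv = FALSE)
  kin <- .kin_setup(me, state$h, state$ps)
  U <- energy_forces(ff, state, top)$U
  E <- kin$KE + U
  if (!cfg$fix_cell)
    E <- E + sum(state$ph^2) / (2 * cfg$W) + cfg$P * det(state$h)
  E
}

#' Instantaneous temperature from the scaled momenta
#'
#' @inheritParams momentum_half_step
#' @return Temperature in K (2 KE / (3N k_B)).
#' @export
instantaneous_temperature <- function(state, model, top) {
  me <- mass_eval(model, positions(state), top, deriv = FALSE)
  kin <- .kin_setup(me, state$h, state$ps)
  2 * kin$KE / (3 * ncol(state$s) * .kB)
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw momenta from the mass-matrix-consistent Boltzmann distribution
#'
#' Velocities are Gaussian with covariance \eqn{k_B T M^{-1}} so the
#' momenta `p = M v` have covariance \eqn{k_B T M}; the scaled momenta are
#' `ps = h^T p`.  With the uniform-scaling constraint the initial cell
#' momenta are drawn inside the allowed one-dimensional subspace.
#'
#' @param state State providing positions and cell (momenta ignored).
#' @param model A mass model.
#' @param top An [topology()].
#' @param T Temperature in K.
#' @param cfg An [integrator_config()] (for `W` and the constraint flags).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return List with `ps` (3 x N) and `ph` (3 x 3).
#' @export
boltzmann_velocities <- function(state, model, top, T, cfg, seed = NULL) {
  stopifnot(T >= 0)
  .with_seed(seed, {
    n <- ncol(state$s)
    if (T == 0) {
      ps <- matrix(0, 3, n)
      ph <- matrix(0, 3, 3)
    } else {
      me <- mass_eval(model, positions(state), top, deriv = FALSE)
      P <- matrix(0, me$d, me$nb)
      for (b in seq_len(me$nb)) {
        Uc <- chol(me$c * me$A[, , b])
        P[, b] <- sqrt(.kB * T) * crossprod(Uc, stats::rnorm(me$d))
      }
      pfull <- .scatter(P, me$idx, me$n3)
      ps <- crossprod(state$h, pfull)
      ph <- matrix(0, 3, 3)
      if (!cfg$fix_cell) {
        if (cfg$uniform_scaling) {
          eta <- sqrt(cfg$W * .kB * T) * stats::rnorm(1)
          ph <- eta * state$h / sqrt(sum(state$h^2))
        } else {
          ph <- matrix(sqrt(cfg$W * .kB * T) * stats::rnorm(9), 3, 3)
        }
      }
    }
    list(ps = ps, ph = ph)
  })
}

# ---------------------------------------------------------------------------
# trajectory driver
# ---------------------------------------------------------------------------

#' Run MTMD dynamics
#'
#' Propagates the state and records frames every `record_every` steps.
#' If a step fails (solver non-convergence, non-finite coordinates, cell
#' inversion), the trajectory returned so far carries
#' `status = "stability failure"` instead of aborting, so time-step scans
#' can treat failures as data.
#'
#' @inheritParams momentum_half_step
#' @param n_steps Number of integration steps.
#' @param record_every Frame recording stride (steps).
#' @param integrator `"symplectic"` (default) or `"explicit"` (the
#'   non-symplectic velocity-based variant, for drift comparisons).
#' @return Object of class `mtmd_trajectory`: positions (unwrapped), cells,
#'   scaled momenta, per-frame conserved quantity, `c_q`, instantaneous
#'   temperature, `det_h`, solver iteration counts, times (fs) and the
#'   final state.
#' @export
run_dynamics <- function(state, model, ff, top, cfg, n_steps,
                         record_every = 1L,
                         integrator = c("symplectic", "explicit")) {
  integrator <- match.arg(integrator)
  if (integrator == "explicit")
    return(.run_explicit(state, model, ff, top, cfg, n_steps, record_every))
  nf <- n_steps %/% record_every + 1L
  n <- ncol(state$s)
  xs <- array(NA_real_, c(3, n, nf))
  hs <- array(NA_real_, c(3, 3, nf))
  pss <- array(NA_real_, c(3, n, nf))
  cons <- cq <- Ti <- deth <- times <- rep(NA_real_, nf)
  fpi <- nwi <- rep(NA_integer_, nf)

  cache <- list(me = mass_eval(model, positions(state), top, deriv = TRUE),
                ff = energy_forces(ff, state, top))
  record <- function(k, st, cache, fp, nw) {
    kin <- .kin_setup(cache$me, st$h, st$ps)
    E <- kin$KE + cache$ff$U
    if (!cfg$fix_cell) E <- E + sum(st$ph^2) / (2 * cfg$W) + cfg$P * det(st$h)
    xs[, , k] <<- st$h %*% st$s
    hs[, , k] <<- st$h
    pss[, , k] <<- st$ps
    cons[k] <<- E
    cq[k] <<- cache$me$c
    Ti[k] <<- 2 * kin$KE / (3 * n * .kB)
    deth[k] <<- det(st$h)
    times[k] <<- st$t
    fpi[k] <<- fp
    nwi[k] <<- nw
  }
  record(1L, state, cache, NA_integer_, NA_integer_)
  status <- "ok"
  k <- 1L
  for (i in seq_len(n_steps)) {
    res <- tryCatch(step_mtmd(state, model, ff, top, cfg, cache),
                    error = function(e) e)
    if (inherits(res, "error") || !all(is.finite(res$state$s))) {
      status <- "stability failure"
      attr(status, "message") <- if (inherits(res, "error"))
        conditionMessage(res) else "non-finite coordinates"
      attr(status, "failed_step") <- i
      break
    }
    state <- res$state
    cache <- res$cache
    if (i %% record_every == 0L) {
      k <- k + 1L
      record(k, state, cache, res$fp_iters, res$newton_iters)
    }
  }
  keep <- seq_len(if (status == "ok") nf else k)
  structure(list(x = xs[, , keep, drop = FALSE],
                 h = hs[, , keep, drop = FALSE],
                 ps = pss[, , keep, drop = FALSE],
                 conserved = cons[keep], c_q = cq[keep], T_inst = Ti[keep],
                 det_h = deth[keep], fp_iters = fpi[keep],
                 newton_iters = nwi[keep], times = times[keep],
                 dt = cfg$dt, record_every = record_every,
                 elements = top$elements, status = status,
                 final_state = state),
            class = "mtmd_trajectory")
}

#' @export
print.mtmd_trajectory <- function(x, ...) {
  nf <- length(x$times)
  cat(sprintf("mtmd trajectory: %d frames, %d atoms, dt = %g fs, %s\n",
              nf, dim(x$x)[2], x$dt, x$status))
  if (nf > 1) {
    cat(sprintf("  conserved quantity band: %.3e eV, <c(q)> = %.6f\n",
                diff(range(x$conserved)), mean(x$c_q)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# explicit (non-symplectic) variant: leapfrog in velocities
# ---------------------------------------------------------------------------

# accelerations from the Lagrangian equations of motion:
#   G vdot_s = -dU/ds + 1/2 (vs^T dG/ds_i vs)_i - (dG/dt) vs
#   W vdot_h = -dU/dh - P det(h) h^-T + (M H vs s^T-type terms) + ...
.explicit_acc <- function(s, h, vs, vh, model, ff, top, cfg) {
  x <- h %*% s
  me <- mass_eval(model, x, top, deriv = TRUE)
  st <- system_state(s, h)
  ffres <- energy_forces(ff, st, top)
  hin <- solve(h)
  n3 <- me$n3
  zv <- h %*% vs                      # H vs per atom
  Zv <- .gather(zv, me$idx)
  AZv <- block_apply_cpp(me$A, Zv)
  quadA <- sum(Zv * AZv)              # zv^T A zv over all blocks
  mzv <- me$c * .scatter(AZv, me$idx, n3)   # M H vs (3 x N)

  if (!is.null(me$dA)) {
    Qv <- block_quad_cpp(me$dA, Zv)
    dcdx <- -(me$c / n3) * me$Tr
    fx <- 0.5 * (me$c * Qv + quadA * dcdx)
    fquad_s <- crossprod(h, .scatter(fx, me$idx, n3))
    # dM/dt
    xdot <- vh %*% s + h %*% vs
    Xd <- .gather(xdot, me$idx)
    dAdt <- block_contract_cpp(me$dA, Xd)
    dcdt <- -(me$c / n3) * sum(me$Tr * Xd)
    dMdt_zv <- me$c * block_apply_cpp(dAdt, Zv) + dcdt * me$c * AZv
    dMdt_zv_full <- .scatter(dMdt_zv, me$idx, n3)
  } else {
    fquad_s <- matrix(0, 3, ncol(s))
    fx <- NULL
    dMdt_zv_full <- matrix(0, 3, ncol(s))
  }
  # (dG/dt) vs = dH^T (M H vs) + H^T (dM/dt) (H vs) + H^T M (dH vs)
  dHvs <- vh %*% vs
  MdHvs <- me$c * .scatter(block_apply_cpp(me$A, .gather(dHvs, me$idx)),
                           me$idx, n3)
  dGdt_vs <- crossprod(vh, mzv) + crossprod(h, dMdt_zv_full) +
    crossprod(h, MdHvs)

  rhs <- -ffres$dU_ds + fquad_s - dGdt_vs
  yr <- t(hin) %*% rhs
  Zr <- block_apply_cpp(me$Ainv, .gather(yr, me$idx)) / me$c
  vdot_s <- hin %*% .scatter(Zr, me$idx, n3)

  vdot_h <- matrix(0, 3, 3)
  if (!cfg$fix_cell) {
    inc <- -ffres$dU_dh - cfg$P * det(h) * t(hin) + mzv %*% t(vs)
    if (!is.null(me$dA)) {
      Qvfull <- .scatter(Qv, me$idx, n3)
      Trfull <- .scatter(me$Tr, me$idx, n3)
      QvH <- Qvfull %*% t(s)
      TrH <- Trfull %*% t(s)
      inc <- inc + 0.5 * (me$c * QvH + quadA * (-(me$c / n3)) * TrH)
    }
    if (cfg$uniform_scaling) inc <- project_uniform_scaling(inc, h)
    vdot_h <- inc / cfg$W
  }
  E <- 0.5 * me$c * quadA + ffres$U
  if (!cfg$fix_cell)
    E <- E + 0.5 * cfg$W * sum(vh^2) + cfg$P * det(h)
  list(vdot_s = vdot_s, vdot_h = vdot_h, E = E, c_q = me$c, U = ffres$U,
       KE = 0.5 * me$c * quadA)
}

.run_explicit <- function(state, model, ff, top, cfg, n_steps, record_every) {
  dt <- cfg$dt_int
  n <- ncol(state$s)
  # convert canonical momenta to velocities
  me <- mass_eval(model, positions(state), top, deriv = FALSE)
  kin <- .kin_setup(me, state$h, state$ps)
  vs <- kin$w
  vh <- if (cfg$fix_cell) matrix(0, 3, 3) else state$ph / cfg$W
  s <- state$s; h <- state$h

  nf <- n_steps %/% record_every + 1L
  xs <- array(NA_real_, c(3, n, nf))
  hs <- array(NA_real_, c(3, 3, nf))
  cons <- cq <- Ti <- deth <- times <- rep(NA_real_, nf)

  a0 <- .explicit_acc(s, h, vs, vh, model, ff, top, cfg)
  xs[, , 1] <- h %*% s; hs[, , 1] <- h
  cons[1] <- a0$E; cq[1] <- a0$c_q; deth[1] <- det(h)
  Ti[1] <- 2 * a0$KE / (3 * n * .kB)
  times[1] <- state$t

  vs_half <- vs + 0.5 * dt * a0$vdot_s
  vh_half <- vh + 0.5 * dt * a0$vdot_h
  acc_prev <- a0
  status <- "ok"
  k <- 1L
  t_now <- state$t
  for (i in seq_len(n_steps)) {
    s <- s + dt * vs_half
    h <- if (cfg$fix_cell) h else h + dt * vh_half
    t_now <- t_now + cfg$dt
    # predictor for the integer-step velocities (velocity-dependent forces)
    vs_pred <- vs_half + 0.5 * dt * acc_prev$vdot_s
    vh_pred <- vh_half + 0.5 * dt * acc_prev$vdot_h
    a1 <- tryCatch(.explicit_acc(s, h, vs_pred, vh_pred, model, ff, top, cfg),
                   error = function(e) e)
    if (inherits(a1, "error") || !all(is.finite(a1$vdot_s))) {
      status <- "stability failure"
      attr(status, "failed_step") <- i
      break
    }
    vs_half <- vs_half + dt * a1$vdot_s
    vh_half <- vh_half + dt * a1$vdot_h
    acc_prev <- a1
    if (i %% record_every == 0L) {
      k <- k + 1L
      xs[, , k] <- h %*% s; hs[, , k] <- h
      cons[k] <- a1$E; cq[k] <- a1$c_q; deth[k] <- det(h)
      Ti[k] <- 2 * a1$KE / (3 * n * .kB)
      times[k] <- t_now
    }
  }
  keep <- seq_len(if (status == "ok") nf else k)
  me_end <- mass_eval(model, h %*% s, top, deriv = FALSE)
  # convert velocities back to canonical momenta for the final state
  zv <- h %*% vs_half
  Pz <- me_end$c * block_apply_cpp(me_end$A, .gather(zv, me_end$idx))
  ps_end <- crossprod(h, .scatter(Pz, me_end$idx, me_end$n3))
  structure(list(x = xs[, , keep, drop = FALSE], h = hs[, , keep, drop = FALSE],
                 ps = NULL, conserved = cons[keep], c_q = cq[keep],
                 T_inst = Ti[keep], det_h = deth[keep],
                 fp_iters = rep(NA_integer_, length(keep)),
                 newton_iters = rep(NA_integer_, length(keep)),
                 times = times[keep], dt = cfg$dt,
                 record_every = record_every, elements = top$elements,
                 status = status,
                 final_state = system_state(s, h, ps_end,
                                            cfg$W * vh_half, t = t_now)),
            class = "mtmd_trajectory")
}
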