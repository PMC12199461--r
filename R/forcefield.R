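# Force fields: a four-parameter nitrogen force field (harmonic bond +
# intermolecular Lennard-Jones) and a toy polyatomic force field (harmonic
# bonds and angles + intermolecular Lennard-Jones).  Energies in eV,
# lengths in Angstrom; gradients are analytic.

#' Nitrogen force field (harmonic bond + Lennard-Jones)
#'
#' The potential is
#' \deqn{E = \sum_{bonded} \tfrac12 K_r (r_{ij}-r_0)^2 +
#'   \sum_{nonbonded} \epsilon[(r_m/r_{ij})^{12} - 2 (r_m/r_{ij})^6]}
#' with the nonbonded sum running over all intermolecular atom pairs within
#' the cutoff.  Defaults are the published N2 parametrization.
#'
#' @param r0 Equilibrium bond length (Angstrom).
#' @param Kr Bond spring constant (eV/Angstrom^2).
#' @param eps Lennard-Jones well depth (eV).
#' @param rm Lennard-Jones minimum position (Angstrom).
#' @param cutoff Nonbonded cutoff (Angstrom); no tail correction.
#' @param shift Shift the pair potential to zero at the cutoff (default
#'   `TRUE`) so the energy is continuous when pairs cross the cutoff; set
#'   `FALSE` for the bare truncated form.
#' @return Object of class `c("n2_force_field", "mtmd_force_field")`.
#' @export
n2_force_field <- function(r0 = 1.0977, Kr = 138.331, eps = 0.003456,
                           rm = 3.614, cutoff = 10, shift = TRUE) {
  stopifnot(r0 > 0, Kr > 0, eps > 0, rm > 0, cutoff > 0)
  structure(list(r0 = r0, Kr = Kr, eps = eps, rm = rm, cutoff = cutoff,
                 shift = shift),
            class = c("n2_force_field", "mtmd_force_field"))
}

#' Toy polyatomic force field
#'
#' Harmonic bonds and harmonic angles within molecules, Lennard-Jones
#' between atoms of different molecules.  A desk-scale surrogate for
#' quantum-mechanical engines, used by the molecular-crystal fixtures.
#'
#' @param bond_k,bond_r0 Per-bond spring constants (eV/A^2) and equilibrium
#'   lengths (A); recycled over the topology's bonds.
#' @param angle_k,angle_0 Per-angle spring constants (eV/rad^2) and
#'   equilibrium angles (rad); recycled over the topology's angles.
#' @param eps,rm Intermolecular Lennard-Jones well depth (eV) and minimum
#'   position (A).
#' @param cutoff Nonbonded cutoff (A).
#' @param shift Shift the pair potential to zero at the cutoff.
#' @return Object of class `c("toy_force_field", "mtmd_force_field")`.
#' @export
toy_force_field <- function(bond_k, bond_r0, angle_k = numeric(0),
                            angle_0 = numeric(0), eps = 0.005, rm = 3.5,
                            cutoff = 9, shift = TRUE) {
  stopifnot(all(bond_k > 0), all(bond_r0 > 0), all(angle_k > 0) || length(angle_k) == 0,
            eps > 0, rm > 0, cutoff > 0)
  structure(list(bond_k = bond_k, bond_r0 = bond_r0, angle_k = angle_k,
                 angle_0 = angle_0, eps = eps, rm = rm, cutoff = cutoff,
                 shift = shift),
            class = c("toy_force_field", "mtmd_force_field"))
}

.min_cell_width <- function(h) {
  v <- abs(det(h))
  widths <- vapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    cr <- .cross3(h[, others[1]], h[, others[2]])
    v / sqrt(sum(cr^2))
  }, numeric(1))
  min(widths)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.check_cutoff <- function(ff, h) {
  w <- .min_cell_width(h)
  if (ff$cutoff >= w / 2)
    stop(sprintf(paste0("nonbonded cutoff %.3f A violates the minimum-image ",
                        "convention (half minimum cell width %.3f A)"),
         ff$cutoff, w / 2))
}

#' Potential energy and analytic gradients
#'
#' Evaluates `U(s, h)` with gradients with respect to the fractional
#' coordinates and the cell matrix.
#'
#' @param ff A force field object.
#' @param state An [system_state()] (momenta ignored).
#' @param top An [topology()].
#' @return List with `U` (eV), `dU_dx` (3 x N, eV/A), `dU_ds` (3 x N) and
#'   `dU_dh` (3 x 3).
#' @export
energy_forces <- function(ff, state, top) UseMethod("energy_forces")

#' @export
energy_forces.n2_force_field <- function(ff, state, top) {
  if (nrow(top$bonds) > 0) {
    sizes <- table(top$molecule_ids)
    if (any(sizes != 2))
      stop("the nitrogen force field requires diatomic molecules only")
  }
  .ff_eval(state$s, state$h, top,
           bond_k = rep(ff$Kr, nrow(top$bonds)),
           bond_r0 = rep(ff$r0, nrow(top$bonds)),
           angles = matrix(integer(0), 0, 3),
           angle_k = numeric(0), angle_0 = numeric(0),
           eps = ff$eps, rm = ff$rm, cutoff = ff$cutoff,
           shift = isTRUE(ff$shift))
}

#' @export
energy_forces.toy_force_field <- function(ff, state, top) {
  nb <- nrow(top$bonds); na <- nrow(top$angles)
  .ff_eval(state$s, state$h, top,
           bond_k = rep_len(ff$bond_k, nb), bond_r0 = rep_len(ff$bond_r0, nb),
           angles = top$angles,
           angle_k = if (na) rep_len(ff$angle_k, na) else numeric(0),
           angle_0 = if (na) rep_len(ff$angle_0, na) else numeric(0),
           eps = ff$eps, rm = ff$rm, cutoff = ff$cutoff,
           shift = isTRUE(ff$shift))
}

.ff_eval <- function(s, h, top, bond_k, bond_r0, angles, angle_k, angle_0,
                     eps, rm, cutoff, shift = TRUE) {
  ffobj <- list(cutoff = cutoff)
  .check_cutoff(ffobj, h)
  ushift <- if (shift) {
    p6 <- (rm / cutoff)^6
    eps * (p6^2 - 2 * p6)
  } else 0
  res <- ff_kernel_cpp(s, h, t(top$bonds) - 1L, bond_k, bond_r0,
                       t(angles) - 1L, angle_k, angle_0,
                       top$molecule_ids, eps, rm, cutoff, ushift)
  if (!is.finite(res$U)) stop("non-finite potential energy")
  list(U = res$U, dU_dx = res$gx, dU_ds = crossprod(h, res$gx),
       dU_dh = res$dU_dh)
}

#' Gradient of the potential energy with respect to the cell matrix
#'
#' @inheritParams energy_forces
#' @return 3 x 3 matrix of derivatives of U w.r.t. the entries of `h` at
#'   fixed fractional coordinates.
#' @export
cell_gradient <- function(ff, state, top) {
  if (abs(det(state$h)) < 1e-12) stop("singular cell matrix")
  energy_forces(ff, state, top)$dU_dh
}

#' Potential energy as a function of Cartesian positions at fixed cell
#'
#' @inheritParams energy_forces
#' @param h Fixed 3 x 3 cell matrix.
#' @param gradient If `TRUE` return the gradient function instead.
#' @return A function mapping a 3N vector (or 3 x N matrix) of Cartesian
#'   positions to the potential energy (eV) or its gradient.
#' @export
energy_function <- function(ff, top, h, gradient = FALSE) {
  force(ff); force(top); force(h)
  hin <- solve(h)
  function(x) {
    x <- matrix(x, nrow = 3)
    st <- system_state(hin %*% x, h)
    res <- energy_forces(ff, st, top)
    if (gradient) as.numeric(res$dU_dx) else res$U
  }
}

#' Finite-difference Hessian of an energy function
#'
#' Symmetrized central-difference Hessian.  When a gradient function is
#' supplied, the Hessian is assembled from central differences of the
#' gradient (2 x 3N evaluations); otherwise from energy evaluations alone.
#'
#' @param x Positions (numeric vector) at which to differentiate.
#' @param energy_fn Function mapping positions to a scalar energy.
#' @param step Displacement step (Angstrom), default 1e-3.
#' @param grad_fn Optional gradient function.
#' @return Symmetric Hessian matrix.
#' @export
fd_hessian <- function(x, energy_fn, step = 1e-3, grad_fn = NULL) {
  stopifnot(step > 0)
  x <- as.numeric(x)
  n <- length(x)
  H <- matrix(0, n, n)
  if (!is.null(grad_fn)) {
    for (i in seq_len(n)) {
      xp <- x; xp[i] <- xp[i] + step
      xm <- x; xm[i] <- xm[i] - step
      gp <- grad_fn(xp); gm <- grad_fn(xm)
      if (!all(is.finite(gp)) || !all(is.finite(gm)))
        stop("non-finite gradient during finite differencing")
      H[, i] <- (gp - gm) / (2 * step)
    }
  } else {
    e0 <- energy_fn(x)
    ep <- em <- numeric(n)
    chk <- function(e) {
      if (!is.finite(e)) stop("non-finite energy during finite differencing")
      e
    }
    for (i in seq_len(n)) {
      xp <- x; xp[i] <- xp[i] + step
      xm <- x; xm[i] <- xm[i] - step
      ep[i] <- chk(energy_fn(xp)); em[i] <- chk(energy_fn(xm))
      H[i, i] <- (ep[i] - 2 * e0 + em[i]) / step^2
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        xpp <- x; xpp[i] <- xpp[i] + step; xpp[j] <- xpp[j] + step
        xmm <- x; xmm[i] <- xmm[i] - step; xmm[j] <- xmm[j] - step
        epp <- chk(energy_fn(xpp)); emm <- chk(energy_fn(xmm))
        H[i, j] <- H[j, i] <-
          (epp - ep[i] - ep[j] + 2 * e0 - em[i] - em[j] + emm) / (2 * step^2)
      }
    }
  }
  (H + t(H)) / 2
}
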