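# Position-dependent mass models.  All models produce a block-diagonal mass
# matrix (one block per molecule) with a constant determinant, so the
# configurational distribution of the modified dynamics stays proportional
# to exp(-U/kT).  Three families:
#   * constant (physical or repartitioned) masses,
#   * the diatomic mode-resolved decomposition (translation/rotation/
#     vibration of each molecule assigned separate masses),
#   * the internal-coordinate Hessian construction
#     M(q) = (w B^T(q) Hq0 B(q) + Mp) c(q),
# where B is the Wilson B matrix of the current geometry, Hq0 a fixed
# reference Hessian in redundant internal coordinates, Mp a constant
# positive definite base matrix and c(q) the determinant-restoring scale.

#' Constant mass model (physical or repartitioned masses)
#'
#' @param top An [topology()].
#' @param repartition If `TRUE`, every atom receives the mean atomic mass
#'   (total mass conserved); otherwise physical masses are used.
#' @return Object of class `c("constant_mass_model", "mass_model")`.
#' @export
constant_mass_model <- function(top, repartition = FALSE) {
  masses <- if (repartition) rep(mean(top$masses), length(top$masses))
            else top$masses
  obj <- structure(list(masses = masses, repartition = repartition),
                   class = c("constant_mass_model", "mass_model"))
  obj
}

#' Mass-repartitioned constant mass matrix
#'
#' Returns the dense constant matrix \eqn{(1/N)(\sum_i m_i) I_{3N}}: every
#' atom carries the mean mass, conserving the total mass.
#'
#' @param top An [topology()].
#' @return Dense 3N x 3N diagonal matrix (u).
#' @export
mass_repartitioned <- function(top) {
  n <- length(top$masses)
  diag(rep(mean(top$masses), 3 * n))
}

#' Diatomic mode-resolved mass model
#'
#' Each diatomic molecule contributes a 6 x 6 block decomposed into three
#' translational modes (mass `m_trans`), two rotational modes (`m_rot`) and
#' one vibrational mode (`m_vib`) along the current bond direction.  The
#' block determinant `m_trans^3 m_rot^2 m_vib` is independent of the
#' geometry, so the determinant constraint holds with `c(q) = 1`.
#'
#' @param m_trans,m_rot,m_vib Mode masses in u (strictly positive).
#' @return Object of class `c("diatomic_mass_model", "mass_model")`.
#' @export
diatomic_mass_model <- function(m_trans, m_rot, m_vib) {
  stopifnot(m_trans > 0, m_rot > 0, m_vib > 0)
  structure(list(m_trans = m_trans, m_rot = m_rot, m_vib = m_vib),
            class = c("diatomic_mass_model", "mass_model"))
}

#' Single 6 x 6 diatomic mass block
#'
#' @param d_hat Unit vector along the bond (atom i to atom j).
#' @param model A [diatomic_mass_model()].
#' @return Symmetric 6 x 6 matrix (coordinates ordered atom i xyz, atom j
#'   xyz).
#' @export
diatomic_block <- function(d_hat, model) {
  d_hat <- as.numeric(d_hat)
  if (abs(sum(d_hat^2) - 1) > 1e-8)
    stop("d_hat must be a unit vector")
  D <- tcrossprod(d_hat)
  I3 <- diag(3)
  diag3 <- 0.5 * (model$m_trans * I3 + model$m_rot * (I3 - D) +
                    model$m_vib * D)
  off3 <- 0.5 * (model$m_trans * I3 - model$m_rot * (I3 - D) -
                   model$m_vib * D)
  rbind(cbind(diag3, off3), cbind(off3, diag3))
}

#' Reference Hessian in redundant internal coordinates
#'
#' Forward-transforms a Cartesian Hessian at a local minimum into internal
#' coordinates, \eqn{H_{q,0} = B^{+T} H_x B^{+}}, using the thresholded
#' pseudoinverse of the Wilson B matrix.  The gradient-weighted
#' second-derivative (K-matrix) term vanishes at a minimum and is omitted;
#' if a nonzero reference gradient is supplied, a warning notes that the
#' omission is no longer exact.  The result is symmetrized and negative
#' near-zero eigenvalues (numerical noise) are clipped at zero so the
#' matrix is positive semidefinite.
#'
#' @param Hx0 Symmetric Cartesian Hessian (eV/A^2 and mixed units).
#' @param eval0 An [evaluate_internals()] result at the reference geometry.
#' @param gradient Optional Cartesian gradient at the reference (eV/A).
#' @param grad_tol Gradient tolerance above which a warning is issued.
#' @param zero_offdiag If `TRUE`, null the off-diagonal elements of the
#'   internal-coordinate Hessian (diagonal variant).
#' @return Symmetric positive semidefinite matrix (n_internal square).
#' @export
reference_hessian_internal <- function(Hx0, eval0, gradient = NULL,
                                       grad_tol = 1e-5,
                                       zero_offdiag = FALSE) {
  if (!is.null(gradient) && max(abs(gradient)) > grad_tol)
    warning(sprintf(paste0("reference gradient max |g| = %.2e exceeds %.1e; ",
                           "omitting the K-matrix term is no longer exact"),
                    max(abs(gradient)), grad_tol))
  Bp <- if (!is.null(eval0$B_pinv)) eval0$B_pinv else thresholded_pinv(eval0$B)
  Hq <- crossprod(Bp, Hx0 %*% Bp)
  Hq <- (Hq + t(Hq)) / 2
  if (zero_offdiag) Hq <- diag(diag(Hq), nrow = nrow(Hq))
  ee <- eigen(Hq, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  Hq <- ee$vectors %*% (vals * t(ee$vectors))
  (Hq + t(Hq)) / 2
}

#' Internal-coordinate Hessian mass model
#'
#' Builds the position-dependent mass matrix
#' \eqn{M(q) = (w B^T(q) H_{q,0} B(q) + M_p)\, c(q)} per molecule, where
#' `Hq0` is held fixed at its reference value and `c(q)` rescales the
#' matrix so that `det M` stays equal to its reference value `D0`
#' (`c(q0) = 1` by construction).
#'
#' @param top An [topology()] whose angle/dihedral lists select the
#'   internal coordinate set (bonds only / bonds+angles / full).
#' @param x0 3 x N reference Cartesian positions at a local minimum
#'   (molecules whole).
#' @param Hx0 Cartesian Hessian at the reference (3N x 3N).
#' @param w Weight in u A^2/eV controlling the Hessian term (default 0.5,
#'   the molecular-crystal recipe; 0.2 is the liquid-water recipe).
#' @param Mp `"physical"` or `"repartitioned"` base mass matrix, or a
#'   per-atom numeric vector of masses (u).
#' @param zero_offdiag Null the off-diagonal internal-coordinate Hessian
#'   entries (diagonal variant).
#' @param gradient0 Optional reference Cartesian gradient, used to warn when
#'   the reference is not a minimum.
#' @return Object of class `c("internal_mass_model", "mass_model")`.
#' @export
internal_hessian_mass_model <- function(top, x0, Hx0, w = 0.5,
                                        Mp = c("physical", "repartitioned"),
                                        zero_offdiag = FALSE,
                                        gradient0 = NULL) {
  stopifnot(w >= 0)
  x0 <- as.matrix(x0)
  n <- ncol(x0)
  if (is.character(Mp)) {
    Mp <- match.arg(Mp)
    mp_atom <- if (Mp == "physical") top$masses else
      rep(mean(top$masses), n)
  } else {
    stopifnot(length(Mp) == n, all(Mp > 0))
    mp_atom <- Mp
  }
  mols <- .internal_model_mols(top, x0, Hx0, mp_atom, zero_offdiag, gradient0)
  obj <- structure(list(w = w, mols = mols$mols, d = mols$d,
                        zero_offdiag = zero_offdiag, mp_atom = mp_atom),
                   class = c("internal_mass_model", "mass_model"))
  # reference determinant (of the unrescaled matrix) fixes c(q0) = 1
  me0 <- mass_eval(obj, x0, top, deriv = FALSE, reference = TRUE)
  obj$logD0 <- me0$logdetA
  obj
}

# per-molecule structures for the C++ block builder
.internal_model_mols <- function(top, x0, Hx0, mp_atom, zero_offdiag,
                                 gradient0) {
  mol_atoms <- .molecule_atoms(top)
  sizes <- lengths(mol_atoms)
  if (length(unique(sizes)) != 1)
    stop("all molecules must have the same number of atoms")
  d <- 3L * sizes[[1]]
  ct <- .coord_table(top)
  mid_of_coord <- top$molecule_ids[ct$atoms[, 1]]
  mols <- vector("list", length(mol_atoms))
  for (m in seq_along(mol_atoms)) {
    atoms <- mol_atoms[[m]]
    vidx <- as.integer(outer(0:2, 3 * (atoms - 1L), "+") + 1L)
    sel <- which(mid_of_coord == m)
    if (length(sel) == 0)
      stop("molecule ", m, " has no internal coordinates")
    type <- ct$type[sel]
    catoms <- ct$atoms[sel, , drop = FALSE]
    local <- match(catoms, atoms)               # NA for padding (-1)
    catoms_local <- matrix(ifelse(is.na(local), 0L, local - 1L),
                           nrow(catoms), 4)
    # reference evaluation and forward Hessian transform for this molecule
    ev0 <- eval_internals_cpp(as.numeric(x0)[vidx], type, catoms_local, FALSE)
    Hx_mol <- Hx0[vidx, vidx, drop = FALSE]
    g_mol <- if (!is.null(gradient0)) as.numeric(gradient0)[vidx] else NULL
    Hq0 <- reference_hessian_internal(
      Hx_mol, list(B = ev0$B), gradient = g_mol, zero_offdiag = zero_offdiag)
    Mp_block <- diag(rep(mp_atom[atoms], each = 3), nrow = d)
    mols[[m]] <- list(vidx = vidx - 1L, type = type,
                      catoms = catoms_local + 0L, Hq0 = Hq0, Mp = Mp_block)
  }
  list(mols = mols, d = d)
}

# ---------------------------------------------------------------------------
# block evaluation (engine interface)
# ---------------------------------------------------------------------------

# variable-index matrix (d x nb): global indices into the flattened 3 x N
# position/momentum arrays, one column per molecule
.block_index <- function(top, d) {
  mol_atoms <- .molecule_atoms(top)
  idx <- vapply(mol_atoms, function(atoms) {
    as.integer(outer(0:2, 3 * (atoms - 1L), "+") + 1L)
  }, integer(d))
  matrix(idx, d, length(mol_atoms))
}

#' Evaluate a mass model at a configuration
#'
#' Produces the block-diagonal mass matrix in its block representation:
#' unscaled blocks `A` (cube d x d x n_mol), their Cartesian derivative
#' tensor `dA`, inverses, the determinant-restoring scale `c` and trace
#' terms used for its derivatives.
#'
#' @param model A mass model.
#' @param x 3 x N Cartesian positions (Angstrom, molecules whole).
#' @param top An [topology()].
#' @param deriv Compute derivative tensors.
#' @param reference Internal flag used while fixing the reference
#'   determinant.
#' @return Object of class `mass_evaluation`.
#' @export
mass_eval <- function(model, x, top, deriv = TRUE, reference = FALSE) {
  UseMethod("mass_eval")
}

.finish_mass_eval <- function(model, A, dA, idx, n3, reference = FALSE) {
  d <- dim(A)[1]; nb <- dim(A)[3]
  Ainv <- cube_inv_cpp(A)
  logdetA <- cube_logdet_cpp(A)
  if (reference || is.null(model$logD0)) {
    cc <- 1
  } else {
    cc <- exp((model$logD0 - logdetA) / n3)
  }
  Tr <- if (!is.null(dA)) block_trace_cpp(dA, Ainv) else NULL
  structure(list(A = A, dA = dA, Ainv = Ainv, logdetA = logdetA, c = cc,
                 Tr = Tr, idx = idx, d = d, nb = nb, n3 = n3),
            class = "mass_evaluation")
}

#' @export
mass_eval.constant_mass_model <- function(model, x, top, deriv = TRUE,
                                          reference = FALSE) {
  mol_atoms <- .molecule_atoms(top)
  sizes <- lengths(mol_atoms)
  if (length(unique(sizes)) != 1)
    stop("all molecules must have the same number of atoms")
  d <- 3L * sizes[[1]]
  nb <- length(mol_atoms)
  idx <- .block_index(top, d)
  A <- array(0, c(d, d, nb))
  for (m in seq_len(nb)) {
    A[, , m] <- diag(rep(model$masses[mol_atoms[[m]]], each = 3), nrow = d)
  }
  me <- .finish_mass_eval(model, A, NULL, idx, 3L * length(top$masses))
  me$c <- 1
  me
}

#' @export
mass_eval.diatomic_mass_model <- function(model, x, top, deriv = TRUE,
                                          reference = FALSE) {
  x <- as.matrix(x)
  bonds <- top$bonds
  if (any(table(top$molecule_ids) != 2))
    stop("diatomic mass model requires diatomic molecules")
  # order bonds by molecule index so blocks align with .block_index
  mid <- top$molecule_ids[bonds[, 1]]
  bonds <- bonds[order(mid), , drop = FALSE]
  res <- diatomic_blocks_cpp(x, t(bonds) - 1L, model$m_trans, model$m_rot,
                             model$m_vib, deriv)
  idx <- vapply(seq_len(nrow(bonds)), function(b) {
    atoms <- bonds[b, ]
    as.integer(outer(0:2, 3 * (atoms - 1L), "+") + 1L)
  }, integer(6))
  me <- .finish_mass_eval(model, res$A, if (deriv) res$dA else NULL,
                          matrix(idx, 6, nrow(bonds)),
                          3L * length(top$masses), reference = reference)
  if (is.null(model$logD0)) {
    # determinant analytically constant: mt^3 mr^2 mv per block
    me$c <- 1
  }
  me
}

#' @export
mass_eval.internal_mass_model <- function(model, x, top, deriv = TRUE,
                                          reference = FALSE) {
  x <- as.matrix(x)
  res <- internal_mass_blocks_cpp(as.numeric(x), model$mols, model$w, deriv)
  idx <- vapply(model$mols, function(m) m$vidx + 1L, integer(model$d))
  .finish_mass_eval(model, res$A, if (deriv) res$dA else NULL,
                    matrix(idx, model$d, length(model$mols)),
                    3L * length(top$masses), reference = reference)
}

# gather a 3 x N array into block layout (d x nb) and back
.gather <- function(mat3N, idx) {
  matrix(as.numeric(mat3N)[idx], nrow(idx), ncol(idx))
}
.scatter <- function(blocks, idx, n3) {
  out <- numeric(n3)
  out[idx] <- blocks
  matrix(out, nrow = 3)
}

# ---------------------------------------------------------------------------
# dense assembly (inspection / validation interfaces)
# ---------------------------------------------------------------------------

#' Assemble the dense mass matrix at a configuration
#'
#' @param model A mass model.
#' @param state An [system_state()].
#' @param top An [topology()].
#' @param deriv Also return the derivative matrices `dM_ds` (list over the
#'   3N fractional coordinates); intended for small systems.
#' @return List with `M` (3N x 3N, u), `c`, and optionally `dM_ds`.
#' @export
build_mass_matrix <- function(model, state, top, deriv = FALSE) {
  x <- positions(state)
  n3 <- 3L * ncol(x)
  me <- mass_eval(model, x, top, deriv = deriv)
  M <- matrix(0, n3, n3)
  for (b in seq_len(me$nb)) {
    vi <- me$idx[, b]
    M[vi, vi] <- me$c * me$A[, , b]
  }
  out <- list(M = M, c = me$c)
  if (deriv) out$dM_ds <- .dense_dM_ds(me, state$h)
  out
}

# dM/ds_{j beta} = c dA/ds + (dc/ds) A over all blocks (dense, small systems)
.dense_dM_ds <- function(me, h) {
  if (is.null(me$dA)) {
    return(replicate(me$n3, matrix(0, me$n3, me$n3), simplify = FALSE))
  }
  n3 <- me$n3
  d <- me$d; nb <- me$nb
  dcdx <- -(me$c / n3) * me$Tr                     # per local x variable
  out <- vector("list", n3)
  A_dense <- matrix(0, n3, n3)
  for (b in seq_len(nb)) A_dense[me$idx[, b], me$idx[, b]] <- me$A[, , b]
  # first build dM/dx for all global Cartesian variables
  dM_dx <- vector("list", n3)
  for (v in seq_len(n3)) dM_dx[[v]] <- (0) # placeholder
  loc_of <- matrix(0L, 2, n3)  # (k, b) for each global variable
  for (b in seq_len(nb)) for (k in seq_len(d)) loc_of[, me$idx[k, b]] <- c(k, b)
  for (v in seq_len(n3)) {
    k <- loc_of[1, v]; b <- loc_of[2, v]
    dm <- matrix(0, n3, n3)
    vi <- me$idx[, b]
    dm[vi, vi] <- me$c * me$dA[, , k, b]
    dm <- dm + dcdx[k, b] * A_dense
    dM_dx[[v]] <- dm
  }
  # chain to fractional coordinates: d/ds_{j,beta} = sum_a h[a,beta] d/dx_{j,a}
  for (j in seq_len(n3 / 3)) {
    for (beta in 1:3) {
      v <- 3 * (j - 1) + beta
      acc <- matrix(0, n3, n3)
      for (a in 1:3) acc <- acc + h[a, beta] * dM_dx[[3 * (j - 1) + a]]
      out[[v]] <- acc
    }
  }
  out
}

#' Mass-weighted metric tensor G and its inverse
#'
#' \eqn{G = H^T M H} with `H` the block-diagonal repetition of the cell
#' matrix over atoms (Cartesian positions `R = h s`).
#'
#' @param M Dense 3N x 3N mass matrix.
#' @param h 3 x 3 cell matrix.
#' @return List with `G` and `Ginv`.
#' @export
build_G <- function(M, h) {
  if (abs(det(h)) < 1e-14) stop("cell matrix must be invertible")
  n <- nrow(M) / 3
  H <- kronecker(diag(n), h)
  G <- crossprod(H, M %*% H)
  G <- (G + t(G)) / 2
  list(G = G, Ginv = chol2inv(chol(G)))
}

#' Derivatives of the inverse metric tensor (dense, for validation)
#'
#' Computes \eqn{\partial G^{-1}/\partial s_i} for every fractional
#' coordinate and \eqn{\partial G^{-1}/\partial h_{ab}} for every cell
#' entry, via \eqn{\partial G^{-1} = -G^{-1} (\partial G) G^{-1}} with the
#' mass-matrix dependence entering through the Wilson-B derivatives and the
#' determinant-restoring scale.
#'
#' @inheritParams build_mass_matrix
#' @return List with `dGinv_ds` (list of 3N matrices) and `dGinv_dh`
#'   (3 x 3 list matrix).
#' @export
dGinv_derivatives <- function(model, state, top) {
  x <- positions(state)
  h <- state$h
  n3 <- 3L * ncol(x)
  me <- mass_eval(model, x, top, deriv = TRUE)
  bm <- build_mass_matrix(model, state, top, deriv = TRUE)
  bg <- build_G(bm$M, h)
  n <- ncol(x)
  H <- kronecker(diag(n), h)
  dGinv_ds <- lapply(bm$dM_ds, function(dM) {
    dG <- crossprod(H, dM %*% H)
    -bg$Ginv %*% dG %*% bg$Ginv
  })
  # cell derivatives: H depends on h; M depends on h through x = h s and c
  dM_dx <- .dense_dM_dx(me)
  s <- state$s
  dGinv_dh <- vector("list", 9)
  dim(dGinv_dh) <- c(3, 3)
  for (a in 1:3) {
    for (b in 1:3) {
      E <- matrix(0, 3, 3); E[a, b] <- 1
      dH <- kronecker(diag(n), E)
      dM <- matrix(0, n3, n3)
      if (!is.null(dM_dx)) {
        for (i in seq_len(n)) {
          v <- 3 * (i - 1) + a
          dM <- dM + s[b, i] * dM_dx[[v]]
        }
      }
      dG <- crossprod(dH, bm$M %*% H) + crossprod(H, bm$M %*% dH) +
        crossprod(H, dM %*% H)
      dGinv_dh[[a, b]] <- -bg$Ginv %*% dG %*% bg$Ginv
    }
  }
  list(dGinv_ds = dGinv_ds, dGinv_dh = dGinv_dh)
}

.dense_dM_dx <- function(me) {
  if (is.null(me$dA)) return(NULL)
  n3 <- me$n3
  dcdx <- -(me$c / n3) * me$Tr
  A_dense <- matrix(0, n3, n3)
  for (b in seq_len(me$nb)) A_dense[me$idx[, b], me$idx[, b]] <- me$A[, , b]
  out <- vector("list", n3)
  for (b in seq_len(me$nb)) {
    vi <- me$idx[, b]
    for (k in seq_len(me$d)) {
      v <- me$idx[k, b]
      dm <- matrix(0, n3, n3)
      dm[vi, vi] <- me$c * me$dA[, , k, b]
      out[[v]] <- dm + dcdx[k, b] * A_dense
    }
  }
  out
}

#' @export
print.mass_evaluation <- function(x, ...) {
  cat(sprintf("mass evaluation: %d blocks of size %d, c = %.6f\n",
              x$nb, x$d, x$c))
  invisible(x)
}
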