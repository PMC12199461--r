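# Shared fixtures and finite-difference utilities for the test suite.
# All fixtures are generated in code; seeds are fixed for reproducibility.

M_N <- 14.007
# analytic harmonic bond frequency of an isolated N2 molecule, ps^-1:
# sqrt(Kr / mu) / (2 pi) with mu = m_N / 2
n2_harmonic_freq <- function(Kr = 138.331, m = M_N, mass_scale = 1) {
  mu <- mass_scale * m / 2
  omega <- sqrt(Kr / mu)                    # rad per internal time unit
  omega / (2 * pi) * 1000 / mtmd_units()$fs_per_time_unit
}

# random bent 4-atom chain with bonds, angles and one dihedral
random_chain4 <- function(seed) {
  set.seed(seed)
  x <- cbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0), c(3.3, 1.5, 1.0)) +
    matrix(rnorm(12, sd = 0.25), 3, 4)
  top <- topology(elements = c("O", "C", "C", "O"),
                  bonds = rbind(c(1, 2), c(2, 3), c(3, 4)),
                  angles = rbind(c(1, 2, 3), c(2, 3, 4)),
                  dihedrals = rbind(c(1, 2, 3, 4)))
  list(x = x, top = top)
}

# small periodic N2 box (n_mol molecules in a cubic cell) with fixed layout
small_n2_box <- function(n_mol = 4, box = 8, seed = 2, r0 = 1.0977) {
  set.seed(seed)
  n_side <- ceiling(n_mol^(1 / 3))
  spacing <- box / n_side
  sites <- as.matrix(expand.grid(seq_len(n_side), seq_len(n_side),
                                 seq_len(n_side)))[seq_len(n_mol), , drop = FALSE]
  centers <- t((sites - 0.5) * spacing)
  x <- matrix(0, 3, 2 * n_mol)
  for (m in seq_len(n_mol)) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    x[, 2 * m - 1] <- centers[, m] - 0.5 * r0 * ax
    x[, 2 * m] <- centers[, m] + 0.5 * r0 * ax
  }
  h <- diag(rep(box, 3))
  top <- build_topology(x, rep("N", 2 * n_mol), h)
  list(x = x, h = h, top = top, s = solve(h, x))
}

# single isolated N2 molecule in a large fixed cell (no LJ partner)
isolated_n2 <- function(box = 25, stretch = 0) {
  h <- diag(rep(box, 3))
  x <- matrix(c(box / 2 - (1.0977 + stretch) / 2, box / 2, box / 2,
                box / 2 + (1.0977 + stretch) / 2, box / 2, box / 2), 3)
  top <- build_topology(x, rep("N", 2), h)
  list(x = x, h = h, top = top, s = solve(h, x))
}

# central finite differences of a vector-valued function
fd_gradient <- function(f, x, step = 1e-6) {
  x <- as.numeric(x)
  out <- NULL
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + step
    xm[j] <- xm[j] - step
    col <- (f(xp) - f(xm)) / (2 * step)
    if (is.null(out)) out <- matrix(0, length(col), length(x))
    out[, j] <- col
  }
  out
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b)) / max(max(abs(b)), floor)
}

# build a minimal trajectory object from arrays (for synthetic-signal tests)
synthetic_trajectory <- function(x, h, dt_fs, elements) {
  structure(list(x = x, h = h, ps = NULL,
                 conserved = rep(0, dim(x)[3]), c_q = rep(1, dim(x)[3]),
                 T_inst = rep(0, dim(x)[3]), det_h = rep(det(h[, , 1]),
                                                         dim(x)[3]),
                 fp_iters = NA, newton_iters = NA,
                 times = (seq_len(dim(x)[3]) - 1) * dt_fs,
                 dt = dt_fs, record_every = 1, elements = elements,
                 status = "ok", final_state = NULL),
            class = "mtmd_trajectory")
}
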