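# Synthetic fixture builders: liquid and gaseous nitrogen boxes at the
# study densities, and a small molecular-crystal surrogate (bent four-atom
# molecules with bonds, angles and a dihedral) exercising the full
# internal-coordinate mass matrix.

#' Build a periodic liquid-nitrogen box
#'
#' Places diatomic molecules with random orientations on a jittered cubic
#' lattice at the liquid density (512 molecules per 32 A box by default;
#' when `box_len` is omitted it is scaled to preserve that density for
#' other molecule counts).  Bond lengths start at the equilibrium value
#' and momenta are drawn from the Boltzmann distribution.  The default
#' initialization temperature of 100 K is calibrated so that, once the
#' vibrational modes have taken up their equipartition share of potential
#' energy and the cell has relaxed, the kinetic temperature settles near
#' 90 K (slightly superheated liquid).
#'
#' @param n_molecules Number of N2 molecules (default 512).
#' @param box_len Cubic box edge (A); default preserves the 512/32^3
#'   density.
#' @param T Initialization temperature (K) for the Boltzmann draw.
#' @param seed Integer seed (deterministic builds).
#' @param model Mass model used for the Boltzmann draw (default physical
#'   constant masses).
#' @param cfg An [integrator_config()] providing `W` and constraint flags
#'   for the cell momenta (default: uniform-scaling NpH at 0.0001 GPa).
#' @param r0 Starting bond length (A).
#' @param jitter Gaussian jitter of lattice sites (A).
#' @return List with `state`, `top` and `box_len`.
#' @export
build_n2_liquid <- function(n_molecules = 512, box_len = NULL, T = 100,
                            seed = 1, model = NULL, cfg = NULL, r0 = 1.0977,
                            jitter = 0.15) {
  if (is.null(box_len)) box_len <- 32 * (n_molecules / 512)^(1 / 3)
  .build_n2_box(n_molecules, box_len, T, seed, model, cfg, r0, jitter)
}

#' Build a periodic nitrogen-gas box
#'
#' Same construction as [build_n2_liquid()] at the gas-phase density (512
#' molecules per 480 A box).  The default initialization temperature of
#' 1630 K yields an equilibrated temperature near 1500 K once the
#' vibrational potential energy takes up its equipartition share (5.5 of
#' 6 kinetic degrees of freedom per molecule retain their energy).
#'
#' @inheritParams build_n2_liquid
#' @return List with `state`, `top` and `box_len`.
#' @export
build_n2_gas <- function(n_molecules = 512, box_len = NULL, T = 1630,
                         seed = 1, model = NULL, cfg = NULL, r0 = 1.0977,
                         jitter = 0.15) {
  if (is.null(box_len)) box_len <- 480 * (n_molecules / 512)^(1 / 3)
  .build_n2_box(n_molecules, box_len, T, seed, model, cfg, r0, jitter)
}

.build_n2_box <- function(n_molecules, box_len, T, seed, model, cfg, r0,
                          jitter) {
  .with_seed(seed, {
    n_side <- ceiling(n_molecules^(1 / 3))
    spacing <- box_len / n_side
    if (spacing < r0 + 2)
      stop("packing infeasible: lattice spacing below molecular size")
    sites <- as.matrix(expand.grid(seq_len(n_side), seq_len(n_side),
                                   seq_len(n_side)))[seq_len(n_molecules), ]
    centers <- t((sites - 0.5) * spacing) +
      matrix(stats::rnorm(3 * n_molecules, sd = jitter), 3)
    x <- matrix(0, 3, 2 * n_molecules)
    for (m in seq_len(n_molecules)) {
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      x[, 2 * m - 1] <- centers[, m] - 0.5 * r0 * ax
      x[, 2 * m] <- centers[, m] + 0.5 * r0 * ax
    }
    h <- diag(rep(box_len, 3))
    elements <- rep("N", 2 * n_molecules)
    top <- build_topology(x, elements, h)
    if (max(top$molecule_ids) != n_molecules || nrow(top$bonds) != n_molecules)
      stop("packing infeasible: spurious intermolecular contacts")
    .check_min_separation(x, h, top, 2.0)
    s <- make_molecules_whole(solve(h, x), top)
    st <- system_state(s, h, t = 0)
    if (is.null(model)) model <- constant_mass_model(top)
    # cell mass 100 u: the cell breathing mode of the nitrogen box then has
    # a ~1 ps period, an order of magnitude slower than the fastest
    # molecular modes retained by the mass models
    if (is.null(cfg)) cfg <- integrator_config(dt = 1, W = 100, P = 1e-4)
    bv <- boltzmann_velocities(st, model, top, T, cfg)
    st$ps <- bv$ps
    st$ph <- bv$ph
    list(state = st, top = top, box_len = box_len)
  })
}

.check_min_separation <- function(x, h, top, dmin) {
  n <- ncol(x)
  s <- solve(h, x)
  pr <- utils::combn(n, 2)
  keep <- top$molecule_ids[pr[1, ]] != top$molecule_ids[pr[2, ]]
  ds <- s[, pr[1, keep], drop = FALSE] - s[, pr[2, keep], drop = FALSE]
  ds <- ds - round(ds)
  d <- sqrt(colSums((h %*% ds)^2))
  if (any(d < dmin))
    stop(sprintf("packing infeasible: intermolecular contact at %.2f A",
                 min(d)))
  invisible(TRUE)
}

#' Default force-field parameters of the toy molecular crystal
#'
#' Bent four-atom molecules (H-O-O-H connectivity): two O-H bonds, one O-O
#' bond, two angles and one dihedral, so the full redundant
#' internal-coordinate set is exercised.
#'
#' @return A [toy_force_field()].
#' @export
toy_crystal_force_field <- function() {
  toy_force_field(bond_k = c(30, 25, 30), bond_r0 = c(0.97, 1.45, 0.97),
                  angle_k = 3, angle_0 = 1.75, eps = 0.02, rm = 3.3,
                  cutoff = 4.4, shift = TRUE)
}

#' Build a relaxed toy molecular crystal
#'
#' Two (or more) bent four-atom molecules in a small periodic cell,
#' relaxed at fixed cell to a local minimum (max gradient below
#' `grad_tol`), with the finite-difference Cartesian Hessian at the
#' minimum.  The relaxed minimum is the reference configuration for the
#' internal-coordinate mass matrix, where omitting the gradient-weighted
#' (K-matrix) term of the Hessian transformation is exact.
#'
#' @param n_molecules Number of molecules (default 2).
#' @param ff Force field (default [toy_crystal_force_field()]).
#' @param seed Integer seed for the starting jitter.
#' @param box_len Cubic cell edge (A).
#' @param grad_tol Relaxation gradient tolerance (eV/A).
#' @return List with `state` (zero momenta), `top`, `hessian` (3N x 3N),
#'   `x0` (relaxed Cartesian positions), `ff` and `gradient` (final
#'   max-norm).
#' @export
build_toy_crystal <- function(n_molecules = 2, ff = toy_crystal_force_field(),
                              seed = 1, box_len = 9.2, grad_tol = 1e-6) {
  .with_seed(seed, {
    template <- cbind(c(-0.75, 0.62, 0), c(0, 0, 0), c(1.45, 0, 0),
                      c(2.2, -0.55, 0.62))   # H O O H, bent with a twist
    centers <- cbind(c(0.3, 0.25, 0.25), c(0.75, 0.72, 0.7),
                     c(0.28, 0.7, 0.75), c(0.72, 0.3, 0.72))
    if (n_molecules > ncol(centers))
      stop("toy crystal supports up to 4 molecules")
    h <- diag(rep(box_len, 3))
    x <- NULL
    for (m in seq_len(n_molecules)) {
      R <- .random_rotation()
      xm <- R %*% (template - rowMeans(template)) +
        box_len * centers[, m] + stats::rnorm(3, sd = 0.05)
      x <- cbind(x, xm)
    }
    elements <- rep(c("H", "O", "O", "H"), n_molecules)
    top <- build_topology(x, elements, h)
    if (nrow(top$bonds) != 3 * n_molecules ||
        max(top$molecule_ids) != n_molecules)
      stop("unexpected bond pattern in the starting geometry")
    efun <- energy_function(ff, top, h)
    gfun <- energy_function(ff, top, h, gradient = TRUE)
    opt <- stats::optim(as.numeric(x), efun, gfun, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-16))
    x1 <- opt$par
    # polish with damped Newton steps on the gradient if needed
    for (it in 1:50) {
      g <- gfun(x1)
      if (max(abs(g)) < grad_tol) break
      H <- fd_hessian(x1, efun, step = 1e-3, grad_fn = gfun)
      dx <- tryCatch(solve(H + diag(1e-6, length(x1)), g),
                     error = function(e) g * 0.1)
      x1 <- x1 - dx
    }
    g <- gfun(x1)
    if (max(abs(g)) >= grad_tol)
      stop(sprintf("relaxation failed: max gradient %.2e eV/A", max(abs(g))))
    x1 <- matrix(x1, 3)
    top1 <- build_topology(x1, elements, h)
    if (!identical(dim(top1$bonds), dim(top$bonds)))
      stop("bond pattern changed during relaxation")
    hess <- fd_hessian(as.numeric(x1), efun, step = 1e-3, grad_fn = gfun)
    st <- system_state(solve(h, x1), h, t = 0)
    list(state = st, top = top1, hessian = hess, x0 = x1, ff = ff,
         gradient = max(abs(g)))
  })
}

.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-8) break
  }
  q <- q / nq
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
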