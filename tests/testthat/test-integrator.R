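# Symplectic generalized-leapfrog integrator: sub-step contracts, implicit
# solver residuals, reduction to Verlet, reversibility, conservation,
# Boltzmann sampling, ensemble consistency.

test_that("uniform-scaling projection is an orthogonal projection", {
  h <- diag(rep(5, 3))
  expect_equal(project_uniform_scaling(3 * h, h), 3 * h)
  shear <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3)   # traceless, orthogonal to h
  expect_equal(project_uniform_scaling(shear, h), matrix(0, 3, 3))
  set.seed(1)
  inc <- matrix(rnorm(9), 3)
  p1 <- project_uniform_scaling(inc, h)
  expect_equal(project_uniform_scaling(p1, h), p1, tolerance = 1e-14)
})

test_that("constant mass and frozen cell reduce to Stoermer-Verlet", {
  box <- small_n2_box(n_mol = 4, box = 8, seed = 2)
  ff <- n2_force_field(cutoff = 3.9)
  cfg <- integrator_config(dt = 1, fix_cell = TRUE)
  model <- constant_mass_model(box$top)
  st <- system_state(box$s, box$h)
  bv <- boltzmann_velocities(st, model, box$top, 90, cfg, seed = 7)
  st$ps <- bv$ps
  tr <- run_dynamics(st, model, ff, box$top, cfg, 50)

  # reference Verlet in Cartesian coordinates
  xx <- positions(st)
  p <- t(solve(st$h)) %*% st$ps
  mass3 <- matrix(rep(box$top$masses, each = 3), 3)
  dtint <- 1 / mtmd_units()$fs_per_time_unit
  gfun <- energy_function(ff, box$top, st$h, gradient = TRUE)
  for (i in 1:50) {
    p <- p - dtint / 2 * matrix(gfun(as.numeric(xx)), 3)
    xx <- xx + dtint * p / mass3
    p <- p - dtint / 2 * matrix(gfun(as.numeric(xx)), 3)
  }
  expect_equal(positions(tr$final_state), xx, tolerance = 1e-12)
  expect_equal(t(solve(st$h)) %*% tr$final_state$ps, p, tolerance = 1e-12)
})

test_that("zero forces leave momenta unchanged and streaming is linear", {
  # widely separated molecules beyond the cutoff, frozen cell
  iso <- isolated_n2()
  ff <- n2_force_field(cutoff = 5)
  cfg <- integrator_config(dt = 2, fix_cell = TRUE)
  model <- constant_mass_model(iso$top)
  st <- system_state(iso$s, iso$h)
  st$ps <- matrix(rep(c(1, 2, 3), 2) * 0.05, 3)   # rigid drift, no stretch
  tr <- run_dynamics(st, model, ff, iso$top, cfg, 20)
  expect_lt(max(abs(tr$final_state$ps - st$ps)), 1e-10)
  # positions advance linearly: s(t) = s0 + t G^-1 ps
  bg <- build_G(diag(rep(iso$top$masses, each = 3)), iso$h)
  v <- matrix(bg$Ginv %*% as.numeric(st$ps), 3)
  t_int <- 40 / mtmd_units()$fs_per_time_unit
  expect_equal(tr$final_state$s, st$s + t_int * v, tolerance = 1e-10)
})

test_that("implicit solves satisfy the residuals they discretize", {
  box <- small_n2_box(n_mol = 4, box = 8, seed = 2)
  ff <- n2_force_field(cutoff = 3.9)
  model <- diatomic_mass_model(M_N, 4 * M_N, 100 * M_N)
  cfg <- integrator_config(dt = 2, W = 50, P = 1e-4)
  st <- system_state(box$s, box$h)
  bv <- boltzmann_velocities(st, model, box$top, 90, cfg, seed = 3)
  st$ps <- bv$ps; st$ph <- bv$ph
  dt2 <- cfg$dt / mtmd_units()$fs_per_time_unit / 2

  mh <- momentum_half_step(st, model, ff, box$top, cfg)
  # independent residual check through the dense dG^-1/ds machinery
  der <- dGinv_derivatives(model, st, box$top)
  ffres <- energy_forces(ff, st, box$top)
  psh <- as.numeric(mh$ps_half)
  fkin <- vapply(seq_along(psh), function(i)
    -0.5 * sum(psh * (der$dGinv_ds[[i]] %*% psh)), numeric(1))
  resid <- psh - as.numeric(st$ps) - dt2 * (fkin - as.numeric(ffres$dU_ds))
  expect_lt(max(abs(resid)), 1e-10)

  pf <- position_full_step(st, mh$ps_half, mh$ph_half, model, box$top, cfg)
  # cell update is explicit
  expect_equal(pf$h, st$h + 2 * dt2 * mh$ph_half / cfg$W)
  # position residual via dense metric tensors at both endpoints
  G0 <- build_G(build_mass_matrix(model, st, box$top)$M, st$h)$Ginv
  st1 <- system_state(pf$s, pf$h)
  G1 <- build_G(build_mass_matrix(model, st1, box$top)$M, pf$h)$Ginv
  rhs <- dt2 * (G0 + G1) %*% as.numeric(mh$ps_half)
  expect_lt(max(abs(as.numeric(pf$s - st$s) - rhs)), 1e-9)

  mf <- momentum_final_half_step(st1, mh$ps_half, mh$ph_half, model, ff,
                                 box$top, cfg)
  der1 <- dGinv_derivatives(model, st1, box$top)
  ffres1 <- energy_forces(ff, st1, box$top)
  fkin1 <- vapply(seq_along(psh), function(i)
    -0.5 * sum(psh * (der1$dGinv_ds[[i]] %*% psh)), numeric(1))
  resid1 <- as.numeric(mf$ps) - psh - dt2 * (fkin1 - as.numeric(ffres1$dU_ds))
  expect_lt(max(abs(resid1)), 1e-10)
})

test_that("the composed step is time-reversible to solver tolerance", {
  box <- small_n2_box(n_mol = 4, box = 8, seed = 2)
  ff <- n2_force_field(cutoff = 3.9)
  model <- diatomic_mass_model(M_N, 4 * M_N, 100 * M_N)
  cfg <- integrator_config(dt = 2, W = 50, P = 1e-4)
  st <- system_state(box$s, box$h)
  bv <- boltzmann_velocities(st, model, box$top, 90, cfg, seed = 3)
  st$ps <- bv$ps; st$ph <- bv$ph
  trF <- run_dynamics(st, model, ff, box$top, cfg, 100)
  back <- trF$final_state
  back$ps <- -back$ps; back$ph <- -back$ph
  trB <- run_dynamics(back, model, ff, box$top, cfg, 100)
  expect_lt(max(abs(trB$final_state$s - st$s)), 1e-9)
  expect_lt(max(abs(trB$final_state$h - st$h)), 1e-9)
  expect_lt(max(abs(trB$final_state$ps + st$ps)), 1e-8)
})

test_that("the conserved quantity evaluates the NpH Hamiltonian", {
  # zero momenta at the potential minimum with P = 0: H = U_min
  tc <- build_toy_crystal(seed = 3)
  cfg <- integrator_config(dt = 1, W = 50, P = 0)
  model <- constant_mass_model(tc$top)
  Umin <- energy_forces(tc$ff, tc$state, tc$top)$U
  expect_equal(conserved_quantity(tc$state, model, tc$ff, tc$top, cfg), Umin)

  # free particle: (1/2) ps^T G^-1 ps equals (1/2) m v^2
  iso <- isolated_n2()
  modeli <- constant_mass_model(iso$top)
  v <- c(0.02, -0.01, 0.03)                      # A per internal time unit
  p_cart <- matrix(rep(iso$top$masses, each = 3) * rep(v, 2), 3)
  st <- system_state(iso$s, iso$h, ps = crossprod(iso$h, p_cart))
  cfg2 <- integrator_config(dt = 1, fix_cell = TRUE)
  ffz <- n2_force_field(cutoff = 5, shift = FALSE)
  H <- conserved_quantity(st, modeli, ffz, iso$top, cfg2)
  expect_equal(H, 0.5 * sum(iso$top$masses) * sum(v^2), tolerance = 1e-10)
})

test_that("Boltzmann momenta satisfy the sampling statistics", {
  cfg <- integrator_config(dt = 1, fix_cell = TRUE)
  box <- small_n2_box(n_mol = 27, box = 14, seed = 1)
  model <- constant_mass_model(box$top)
  st <- system_state(box$s, box$h)

  bv0 <- boltzmann_velocities(st, model, box$top, 0, cfg, seed = 1)
  expect_equal(max(abs(bv0$ps)), 0)

  Tset <- 90
  kB <- mtmd_units()$k_B
  vs <- NULL
  KE <- numeric(0)
  for (k in 1:20) {
    bv <- boltzmann_velocities(st, model, box$top, Tset, cfg, seed = 100 + k)
    p_cart <- t(solve(st$h)) %*% bv$ps
    vs <- cbind(vs, p_cart / M_N)
    me <- mass_eval(model, positions(st), box$top, deriv = FALSE)
    G <- build_G(diag(rep(M_N, 3 * ncol(st$s))), st$h)
    KE <- c(KE, 0.5 * sum(as.numeric(bv$ps) * (G$Ginv %*% as.numeric(bv$ps))))
  }
  # per-component velocity variance kB T / m within 3 standard errors
  n_samp <- length(vs)
  var_hat <- mean(vs^2)
  var_th <- kB * Tset / M_N
  se <- var_th * sqrt(2 / n_samp)
  expect_lt(abs(var_hat - var_th), 3 * se)
  # equipartition: mean kinetic energy (3N/2) kB T
  ke_th <- 1.5 * ncol(st$s) * kB * Tset
  se_ke <- ke_th * sqrt(2 / (3 * ncol(st$s) * length(KE)))
  expect_lt(abs(mean(KE) - ke_th), 3 * se_ke)

  # mass-matrix-consistent draw: vibrational mode variance scales with m_vib
  modelv <- diatomic_mass_model(M_N, M_N, 100 * M_N)
  stretch <- numeric(0)
  for (k in 1:200) {
    bv <- boltzmann_velocities(st, modelv, box$top, Tset, cfg, seed = 500 + k)
    p_cart <- t(solve(st$h)) %*% bv$ps
    x <- positions(st)
    for (m in 1:5) {
      at <- box$top$bonds[m, ]
      d <- x[, at[2]] - x[, at[1]]; d <- d / sqrt(sum(d^2))
      vrel <- sum(d * (p_cart[, at[2]] - p_cart[, at[1]])) / (100 * M_N)
      stretch <- c(stretch, vrel)
    }
  }
  # relative bond-velocity variance: 2 kB T / m_vib
  var_s <- mean(stretch^2)
  var_s_th <- 2 * kB * Tset / (100 * M_N)
  expect_lt(abs(var_s - var_s_th), 4 * var_s_th * sqrt(2 / length(stretch)))
})

test_that("uniform-scaling initial cell momenta stay in the subspace", {
  box <- small_n2_box(n_mol = 4, box = 8, seed = 2)
  cfg <- integrator_config(dt = 1, W = 50, P = 1e-4, uniform_scaling = TRUE)
  model <- constant_mass_model(box$top)
  st <- system_state(box$s, box$h)
  bv <- boltzmann_velocities(st, model, box$top, 90, cfg, seed = 9)
  expect_equal(project_uniform_scaling(bv$ph, st$h), bv$ph, tolerance = 1e-12)
})

test_that("solver failure carries an informative error", {
  box <- small_n2_box(n_mol = 4, box = 8, seed = 2)
  ff <- n2_force_field(cutoff = 3.9)
  model <- diatomic_mass_model(M_N, 4 * M_N, 100 * M_N)
  cfg <- integrator_config(dt = 60, W = 50, P = 1e-4, fp_max_iter = 5)
  st <- system_state(box$s, box$h)
  bv <- boltzmann_velocities(st, model, box$top, 300, cfg, seed = 3)
  st$ps <- bv$ps; st$ph <- bv$ph
  expect_error(
    for (i in 1:50) st <- step_mtmd(st, model, ff, box$top, cfg)$state,
    "converge")
})

test_that("explicit and symplectic integrators coincide for constant mass", {
  box <- small_n2_box(n_mol = 4, box = 8, seed = 2)
  ff <- n2_force_field(cutoff = 3.9)
  cfg <- integrator_config(dt = 1, fix_cell = TRUE)
  model <- constant_mass_model(box$top)
  st <- system_state(box$s, box$h)
  bv <- boltzmann_velocities(st, model, box$top, 90, cfg, seed = 7)
  st$ps <- bv$ps
  trS <- run_dynamics(st, model, ff, box$top, cfg, 40)
  trE <- run_dynamics(st, model, ff, box$top, cfg, 40, integrator = "explicit")
  expect_equal(trE$final_state$s, trS$final_state$s, tolerance = 1e-8)
})

test_that("MTMD with constant determinant samples the same configurations", {
  # double-well bond potential: the configurational distribution must be
  # unchanged when the vibrational mass is scaled (det M stays constant)
  dw_ff <- structure(list(A = 40, r0 = 1.2, d = 0.15),
                     class = c("dw_force_field", "mtmd_force_field"))
  registerS3method(
    "energy_forces", "dw_force_field",
    function(ff, state, top) {
      x <- positions(state)
      u <- x[, 2] - x[, 1]
      r <- sqrt(sum(u^2))
      y <- (r - ff$r0)^2 - ff$d^2
      dU_dr <- 4 * ff$A * y * (r - ff$r0)
      g <- dU_dr * u / r
      gx <- cbind(-g, g)
      list(U = ff$A * y^2, dU_dx = gx,
           dU_ds = crossprod(state$h, gx),
           dU_dh = gx %*% t(state$s))
    },
    envir = asNamespace("mtmd"))

  h <- diag(rep(20, 3))
  x <- matrix(c(9.4, 10, 10, 10.75, 10, 10), 3)
  top <- build_topology(x, c("N", "N"), h, scale = 1.35)
  sample_r <- function(model, nrun = 25, nstep = 320) {
    cfg <- integrator_config(dt = 1, fix_cell = TRUE)
    per_run <- numeric(nrun)
    for (k in seq_len(nrun)) {
      st <- system_state(solve(h, x), h)
      bv <- boltzmann_velocities(st, model, top, 400, cfg, seed = 2000 + k)
      st$ps <- bv$ps
      tr <- run_dynamics(st, model, dw_ff, top, cfg, nstep, record_every = 4)
      d <- tr$x[, 2, ] - tr$x[, 1, ]
      r <- sqrt(colSums(matrix(d, 3)^2))[-(1:20)]
      per_run[k] <- mean(r)
    }
    per_run
  }
  r_md <- sample_r(constant_mass_model(top))
  r_mt <- sample_r(diatomic_mass_model(M_N, 2 * M_N, 9 * M_N))
  se <- sqrt(var(r_md) / length(r_md) + var(r_mt) / length(r_mt))
  expect_lt(abs(mean(r_md) - mean(r_mt)), 3.5 * se + 1e-4)
})
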