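# Mass models: diatomic mode decomposition, internal-coordinate Hessian
# construction, determinant constraint, metric tensor and its derivatives.

test_that("diatomic block reduces to m I6 for equal mode masses", {
  blk <- diatomic_block(c(0, 0, 1), diatomic_mass_model(14, 14, 14))
  expect_equal(blk, 14 * diag(6))
  expect_error(diatomic_block(c(1, 1, 0), diatomic_mass_model(1, 1, 1)),
               "unit")
})

test_that("diatomic block has the mode eigenstructure and determinant", {
  d <- c(1, 2, 2) / 3
  model <- diatomic_mass_model(14, 56, 1400)
  blk <- diatomic_block(d, model)
  expect_equal(blk, t(blk))
  ev <- sort(eigen(blk, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, c(14, 14, 14, 56, 56, 1400), tolerance = 1e-12)
  expect_equal(det(blk), 14^3 * 56^2 * 1400, tolerance = 1e-9)
})

test_that("mode projectors are idempotent, orthogonal and complete", {
  d <- c(0.6, -0.64, 0.48); d <- d / sqrt(sum(d^2))
  # recover each projector from blocks with indicator-like masses
  base <- diatomic_block(d, diatomic_mass_model(1, 1, 1))
  Pt <- diatomic_block(d, diatomic_mass_model(2, 1, 1)) - base
  Pr <- diatomic_block(d, diatomic_mass_model(1, 2, 1)) - base
  Pv <- diatomic_block(d, diatomic_mass_model(1, 1, 2)) - base
  for (P in list(Pt, Pr, Pv)) expect_equal(P %*% P, P, tolerance = 1e-12)
  expect_lt(max(abs(Pt %*% Pr)), 1e-12)
  expect_lt(max(abs(Pt %*% Pv)), 1e-12)
  expect_lt(max(abs(Pr %*% Pv)), 1e-12)
  expect_equal(Pt + Pr + Pv, diag(6), tolerance = 1e-12)
})

test_that("reference Hessian transform reduces correctly for a diatomic", {
  iso <- isolated_n2()
  ff <- n2_force_field()
  efun <- energy_function(ff, iso$top, iso$h)
  gfun <- energy_function(ff, iso$top, iso$h, gradient = TRUE)
  Hx <- fd_hessian(as.numeric(iso$x), efun, grad_fn = gfun)
  ev0 <- evaluate_internals(iso$top, iso$x)
  Hq <- reference_hessian_internal(Hx, ev0)
  expect_equal(dim(Hq), c(1, 1))
  expect_equal(Hq[1, 1], 138.331, tolerance = 1e-4)

  expect_equal(reference_hessian_internal(matrix(0, 6, 6), ev0),
               matrix(0, 1, 1))
  expect_warning(
    reference_hessian_internal(Hx, ev0, gradient = rep(0.1, 6)),
    "K-matrix")
})

test_that("back transform reproduces the internal-subspace projection", {
  tc <- build_toy_crystal(seed = 3)
  mol_atoms <- which(tc$top$molecule_ids == 1)
  vidx <- as.numeric(outer(0:2, 3 * (mol_atoms - 1), "+") + 1)
  topm <- topology(tc$top$elements[mol_atoms],
                   bonds = matrix(match(tc$top$bonds[1:3, ], mol_atoms), ncol = 2),
                   angles = matrix(match(tc$top$angles[1:2, ], mol_atoms), ncol = 3),
                   dihedrals = matrix(match(tc$top$dihedrals[1, ], mol_atoms),
                                      ncol = 4))
  xm <- tc$x0[, mol_atoms]
  evm <- evaluate_internals(topm, xm, pinv = TRUE)
  Hxm <- tc$hessian[vidx, vidx]
  Hq <- reference_hessian_internal(Hxm, evm)
  Bp <- evm$B_pinv
  P <- Bp %*% evm$B                     # projector onto the internal subspace
  back <- t(evm$B) %*% Hq %*% evm$B
  expect_equal(back, t(P) %*% Hxm %*% P, tolerance = 1e-7)
  # positive semidefinite by construction
  ev <- eigen(back, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9)
})

test_that("zero_offdiag nulls the internal-coordinate couplings", {
  tc <- build_toy_crystal(seed = 3)
  m1 <- internal_hessian_mass_model(tc$top, tc$x0, tc$hessian, w = 0.5)
  m2 <- internal_hessian_mass_model(tc$top, tc$x0, tc$hessian, w = 0.5,
                                    zero_offdiag = TRUE)
  Hq1 <- m1$mols[[1]]$Hq0
  Hq2 <- m2$mols[[1]]$Hq0
  expect_false(isTRUE(all.equal(Hq1, Hq2)))
  off <- Hq2; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-12)
})

test_that("mass repartitioning preserves the total mass", {
  top5 <- topology(c("C", "H", "H", "H", "H"),
                   bonds = rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)),
                   masses = c(12, 1, 1, 1, 1))
  M <- mass_repartitioned(top5)
  expect_equal(M, 3.2 * diag(15))
  expect_equal(sum(diag(M)), 3 * sum(top5$masses))
  topeq <- topology(c("N", "N"), bonds = rbind(c(1, 2)), masses = c(7, 7))
  expect_equal(mass_repartitioned(topeq), 7 * diag(6))
})

test_that("determinant constraint holds with c(q0) = 1", {
  tc <- build_toy_crystal(seed = 3)
  model <- internal_hessian_mass_model(tc$top, tc$x0, tc$hessian, w = 0.5)
  st0 <- tc$state
  bm0 <- build_mass_matrix(model, st0, tc$top)
  expect_equal(bm0$c, 1, tolerance = 1e-13)   # fixed to 1 at the reference
  D0 <- det(bm0$M)

  set.seed(1)
  for (k in 1:5) {
    st <- st0
    st$s <- st$s + matrix(rnorm(length(st$s), sd = 0.01), 3)
    bm <- build_mass_matrix(model, st, tc$top)
    expect_lt(abs(det(bm$M) / D0 - 1), 1e-10)
    ev <- eigen(bm$M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }

  # w = 0 degenerates to the constant base matrix with c = 1
  m0 <- internal_hessian_mass_model(tc$top, tc$x0, tc$hessian, w = 0)
  bmw0 <- build_mass_matrix(m0, st0, tc$top)
  expect_equal(bmw0$c, 1)
  expect_equal(bmw0$M, diag(rep(tc$top$masses, each = 3)))
})

test_that("mass matrix blocks have no cross-molecule coupling", {
  tc <- build_toy_crystal(seed = 3)
  model <- internal_hessian_mass_model(tc$top, tc$x0, tc$hessian, w = 0.5)
  bm <- build_mass_matrix(model, tc$state, tc$top)
  a1 <- which(tc$top$molecule_ids == 1)
  a2 <- which(tc$top$molecule_ids == 2)
  v1 <- as.numeric(outer(0:2, 3 * (a1 - 1), "+") + 1)
  v2 <- as.numeric(outer(0:2, 3 * (a2 - 1), "+") + 1)
  expect_equal(max(abs(bm$M[v1, v2])), 0)
})

test_that("metric tensor G and its inverse behave as a congruence", {
  # cubic cell with scalar masses: G = m a^2 I
  a <- 7.3; m <- 14
  M <- m * diag(6)
  bg <- build_G(M, a * diag(3))
  expect_equal(bg$G, m * a^2 * diag(6))
  expect_equal(bg$Ginv %*% bg$G, diag(6), tolerance = 1e-12)

  set.seed(6)
  R <- matrix(rnorm(36), 6)
  Mpd <- crossprod(R) + 6 * diag(6)
  h <- diag(3) * 5 + matrix(rnorm(9, sd = 0.2), 3)
  bg2 <- build_G(Mpd, h)
  expect_gt(min(eigen(bg2$G, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(bg2$Ginv %*% bg2$G, diag(6), tolerance = 1e-10)
})

test_that("analytic dG^-1 derivatives match finite differences", {
  tc <- build_toy_crystal(seed = 3)
  model <- internal_hessian_mass_model(tc$top, tc$x0, tc$hessian, w = 0.5)
  st <- tc$state
  st$s <- st$s + matrix(rnorm(length(st$s), sd = 0.005), 3)
  der <- dGinv_derivatives(model, st, tc$top)
  n <- ncol(st$s)
  ginv_of <- function(sv, hv) {
    st2 <- system_state(matrix(sv, 3, n), matrix(hv, 3, 3))
    build_G(build_mass_matrix(model, st2, tc$top)$M, st2$h)$Ginv
  }
  hstep <- 1e-5
  for (j in c(1, 8, 17, 24)) {
    sp <- as.numeric(st$s); sm <- sp
    sp[j] <- sp[j] + hstep; sm[j] <- sm[j] - hstep
    fd <- (ginv_of(sp, as.numeric(st$h)) - ginv_of(sm, as.numeric(st$h))) /
      (2 * hstep)
    expect_lt(max_rel_err(der$dGinv_ds[[j]], fd), 1e-5)
  }
  for (j in c(1, 5, 7)) {
    hp <- as.numeric(st$h); hm <- hp
    hp[j] <- hp[j] + hstep; hm[j] <- hm[j] - hstep
    fd <- (ginv_of(as.numeric(st$s), hp) - ginv_of(as.numeric(st$s), hm)) /
      (2 * hstep)
    a <- (j - 1) %% 3 + 1; b <- (j - 1) %/% 3 + 1
    expect_lt(max_rel_err(der$dGinv_dh[[a, b]], fd), 1e-5)
  }
  # constant masses: position derivatives vanish identically
  derc <- dGinv_derivatives(constant_mass_model(tc$top), st, tc$top)
  expect_equal(max(abs(derc$dGinv_ds[[5]])), 0)
})

test_that("the construction lowers the highest mass-weighted frequency", {
  tc <- build_toy_crystal(seed = 3)
  Mp <- diag(rep(tc$top$masses, each = 3))
  f_phys <- mass_weighted_frequencies(tc$hessian, Mp)$f_max
  model <- internal_hessian_mass_model(tc$top, tc$x0, tc$hessian, w = 0.5)
  M <- build_mass_matrix(model, tc$state, tc$top)$M
  f_mtmd <- mass_weighted_frequencies(tc$hessian, M)$f_max
  expect_lt(f_mtmd, f_phys)
})
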