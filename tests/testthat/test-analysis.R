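# Analysis machinery: spectra, mass-weighted frequencies, stability scans,
# RDF, diffusion fits, transition detection.

test_that("spectrum frequency axis is exact for injected tones", {
  r0 <- 1.0977
  for (case in list(c(f = 10, dt = 2), c(f = 35, dt = 1),
                    c(f = 4, dt = 5))) {
    f <- case[["f"]]; dtf <- case[["dt"]]
    nf <- 1024
    tt <- (seq_len(nf) - 1) * dtf / 1000           # ps
    h <- diag(rep(20, 3))
    x <- array(0, c(3, 2, nf))
    for (k in seq_len(nf)) {
      r <- r0 + 0.01 * cos(2 * pi * f * tt[k])
      x[, 1, k] <- c(10 - r / 2, 10, 10)
      x[, 2, k] <- c(10 + r / 2, 10, 10)
    }
    traj <- synthetic_trajectory(x, array(h, c(3, 3, nf)), dtf, c("N", "N"))
    top <- topology(c("N", "N"), bonds = rbind(c(1, 2)))
    sp <- mode_filtered_spectrum(traj, top, "vib")
    bin <- 1 / (max(traj$times) / 1000)
    expect_lt(abs(sp$peak_frequency - f), 1.5 * bin)
  }
  # too few frames
  short <- synthetic_trajectory(array(0, c(3, 2, 100)),
                                array(diag(3), c(3, 3, 100)), 1, c("N", "N"))
  expect_error(mode_filtered_spectrum(short,
                                      topology(c("N", "N"),
                                               bonds = rbind(c(1, 2))),
                                      "vib"),
               "frames")
})

test_that("isolated-molecule vibrational peak matches the harmonic law", {
  iso <- isolated_n2(stretch = 0.01)
  ff <- n2_force_field(cutoff = 5)
  cfg <- integrator_config(dt = 1, fix_cell = TRUE)

  run_peak <- function(model) {
    st <- system_state(iso$s, iso$h)
    bv <- boltzmann_velocities(st, model, iso$top, 90, cfg, seed = 6)
    st$ps <- bv$ps
    tr <- run_dynamics(st, model, ff, iso$top, cfg, 1200, record_every = 2)
    mode_filtered_spectrum(tr, iso$top, "vib", min_frames = 500)$peak_frequency
  }
  f_std <- run_peak(constant_mass_model(iso$top))
  f_ref <- n2_harmonic_freq()
  expect_lt(abs(f_std - f_ref) / f_ref, 0.02)

  # 100-fold vibrational mass: peak at exactly one tenth (freq ~ mass^-1/2)
  f_heavy <- run_peak(diatomic_mass_model(M_N, M_N, 100 * M_N))
  expect_lt(abs(f_heavy - f_ref / 10) / (f_ref / 10), 0.05)
})

test_that("mass-weighted frequencies solve the generalized eigenproblem", {
  # isotropic case: all omega = sqrt(k/m)
  k <- 5; m <- 4
  fr <- mass_weighted_frequencies(k * diag(6), m * diag(6))
  omega_ps <- sqrt(k / m) * 1000 / mtmd_units()$fs_per_time_unit
  expect_equal(fr$omega, rep(omega_ps, 6), tolerance = 1e-10)
  expect_equal(fr$f_max, omega_ps / (2 * pi), tolerance = 1e-10)
  expect_equal(fr$dt_rule, (1000 / fr$f_max) / 10)

  # mass proportional to the Hessian: all frequencies equal
  set.seed(2)
  R <- matrix(rnorm(144), 12)
  H <- crossprod(R) + 12 * diag(12)
  lambda <- 2.5
  fr2 <- mass_weighted_frequencies(H, H / lambda)
  expect_lt(diff(range(fr2$omega)), 1e-8 * max(fr2$omega))

  # random symmetric pair vs a direct generalized eigensolve
  R2 <- matrix(rnorm(144), 12)
  M <- crossprod(R2) + 12 * diag(12)
  Hs <- (H + t(H)) / 2 - 8 * diag(12)             # make some modes negative
  fr3 <- mass_weighted_frequencies(Hs, M)
  gev <- sort(Re(eigen(solve(M, Hs), only.values = TRUE)$values))
  scale <- (1000 / mtmd_units()$fs_per_time_unit)^2
  expect_equal(sort(fr3$omega^2)[gev > 0], gev[gev > 0] * scale,
               tolerance = 1e-8)
  expect_equal(fr3$n_imaginary, sum(gev < 0))
})

test_that("stability scan brackets the harmonic Verlet bound", {
  iso <- isolated_n2()
  ff <- n2_force_field(cutoff = 5)
  model <- constant_mass_model(iso$top)
  runner <- function(dt_fs, n_steps) {
    cfg <- integrator_config(dt = dt_fs, fix_cell = TRUE)
    st <- system_state(iso$s, iso$h)
    bv <- boltzmann_velocities(st, model, iso$top, 90, cfg, seed = 2)
    st$ps <- bv$ps
    run_dynamics(st, model, ff, iso$top, cfg, n_steps,
                 record_every = max(1L, n_steps %/% 500))
  }
  grid <- seq(3.5, 5.5, by = 0.25)
  res <- max_stable_dt(runner, grid, 2000)
  dt_bound <- 2 / (2 * pi * n2_harmonic_freq() / 1000)   # fs
  expect_lt(abs(res$dt_max - dt_bound), 0.25 + 1e-9)
  # far below any instability the scan returns the top of the grid
  res_low <- max_stable_dt(runner, c(0.25, 0.5, 1), 2000)
  expect_equal(res_low$dt_max, 1)
})

test_that("radial distribution function is normalized and peaked correctly", {
  set.seed(4)
  # ideal gas: g ~ 1 away from zero
  n <- 250; L <- 12
  nf <- 8
  x <- array(runif(3 * n * nf) * L, c(3, n, nf))
  h <- array(diag(rep(L, 3)), c(3, 3, nf))
  traj <- synthetic_trajectory(x, h, 1, rep("Ar", n))
  g <- rdf(traj, r_max = 5.5, n_bins = 40)
  expect_lt(max(abs(g$g[g$r > 1.5] - 1)), 0.15)
  # normalization: integral of g rho 4 pi r^2 dr counts neighbors
  rho <- n / L^3
  dr <- diff(g$r[1:2])
  n_in <- sum(g$g * 4 * pi * g$r^2 * dr) * rho
  n_exact <- sum(4 * pi * g$r^2 * dr) * rho        # ideal count to r_max
  expect_lt(abs(n_in - n_exact) / n_exact, 0.05)

  # simple cubic lattice: first peak at the lattice constant
  a <- 3
  sites <- as.matrix(expand.grid(0:3, 0:3, 0:3)) * a
  xs <- array(t(sites), c(3, nrow(sites), 1))
  trajs <- synthetic_trajectory(xs, array(diag(rep(12, 3)), c(3, 3, 1)),
                                1, rep("Ar", nrow(sites)))
  gs <- rdf(trajs, r_max = 5, n_bins = 50)
  expect_equal(gs$r[which.max(gs$g)], a, tolerance = 0.05)
})

test_that("diffusion fit recovers a known Brownian coefficient", {
  # frozen atoms: D = 0
  xf <- array(rep(matrix(rnorm(3 * 16), 3), 50), c(3, 16, 50))
  trajf <- synthetic_trajectory(xf, array(diag(rep(100, 3)), c(3, 3, 50)),
                                50, rep("O", 16))
  fit0 <- diffusion_fit(trajf, origin_stride = 5)
  expect_equal(fit0$D, 0, tolerance = 1e-12)

  # Brownian walkers with D = 0.15 A^2/ps
  set.seed(9)
  D <- 0.15; dtf <- 50; nf <- 200; nw <- 64
  sigma <- sqrt(2 * D * dtf / 1000)
  steps <- array(rnorm(3 * nw * (nf - 1), sd = sigma), c(3, nw, nf - 1))
  xb <- array(0, c(3, nw, nf))
  for (k in 2:nf) xb[, , k] <- xb[, , k - 1] + steps[, , k - 1]
  trajb <- synthetic_trajectory(xb, array(diag(rep(100, 3)), c(3, 3, nf)),
                                dtf, rep("O", nw))
  fitb <- diffusion_fit(trajb, origin_stride = 5)
  expect_lt(abs(fitb$D - D) / D, 0.10)
  expect_false(fitb$ballistic)

  # ballistic motion is flagged
  v <- matrix(rnorm(3 * 16, sd = 0.3), 3, 16)
  xl <- array(0, c(3, 16, 100))
  for (k in 2:100) xl[, , k] <- xl[, , k - 1] + v * dtf / 1000
  trajl <- synthetic_trajectory(xl, array(diag(rep(100, 3)), c(3, 3, 100)),
                                dtf, rep("O", 16))
  expect_true(diffusion_fit(trajl, origin_stride = 5)$ballistic)
})

test_that("transition detector counts crossings and applies exclusions", {
  # two rigid rods rotating against each other
  nf <- 1000
  make_traj <- function(angle_deg, kink_deg = 0) {
    x <- array(0, c(3, 8, nf))
    for (k in seq_len(nf)) {
      th <- angle_deg[k] * pi / 180
      # molecule 1 along x (two 2-atom groups)
      x[, 1, k] <- c(0, 0, 0); x[, 2, k] <- c(1, 0, 0)
      x[, 3, k] <- c(2, 0, 0); x[, 4, k] <- c(3, 0, 0)
      # molecule 2 rotated by th in the xy plane, possibly kinked
      dirn <- c(cos(th), sin(th), 0)
      x[, 5, k] <- c(0, 3, 0); x[, 6, k] <- x[, 5, k] + dirn
      kk <- kink_deg[k] * pi / 180
      dir2 <- c(cos(th + kk), sin(th + kk), 0)
      x[, 7, k] <- x[, 6, k] + dir2; x[, 8, k] <- x[, 7, k] + dir2
    }
    synthetic_trajectory(x, array(diag(rep(50, 3)), c(3, 3, nf)), 1,
                         rep("C", 8))
  }
  spec <- list(
    list(axis = list(1:2, 3:4), kink = list(list(1, 2), list(3, 4))),
    list(axis = list(5:6, 7:8), kink = list(list(5, 6), list(7, 8))))

  # parallel throughout: no events
  tr0 <- make_traj(rep(0, nf), rep(0, nf))
  rep0 <- transition_detector(tr0, spec)
  expect_equal(nrow(rep0$events), 0)

  # ramp 0 -> 90 degrees over 500 frames: exactly one event near the crossing
  ramp <- c(seq(0, 90, length.out = 500), rep(90, nf - 500))
  tr1 <- make_traj(ramp, rep(0, nf))
  rep1 <- transition_detector(tr1, spec, window = 100)
  expect_equal(nrow(rep1$events), 1)
  crossing <- which(ramp >= 80)[1]
  expect_lt(abs(rep1$events$step[1] - crossing), 60)

  # a 35-degree kink during the crossing converts the event to an exclusion
  tr2 <- make_traj(ramp, rep(35, nf))
  rep2 <- transition_detector(tr2, spec, window = 100)
  expect_equal(nrow(rep2$events), 0)
  expect_equal(rep2$excluded$reason[1], "kink")

  # cell-shape predicate exclusion
  rep3 <- transition_detector(tr1, spec, window = 100,
                              cell_predicate = function(h) FALSE)
  expect_equal(nrow(rep3$events), 0)
  expect_equal(rep3$excluded$reason[1], "cell")
})
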