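# Trajectory analysis: mode-filtered power spectra, mass-weighted Hessian
# frequencies and the time-step rule, maximum-stable-time-step scans, radial
# distribution functions, mean-squared-displacement diffusion fits and the
# polymorph-transition detector.

# frame sampling interval in ps
.frame_dt_ps <- function(traj) traj$dt * traj$record_every / 1000

#' Mode-filtered power spectrum of atomic motions
#'
#' Per-molecule scalar signals are extracted (translation: center-of-mass
#' coordinates; rotation: cosine of the angle between the molecular axis
#' and the laboratory z axis; vibration: bond lengths), differentiated
#' twice in time by central differences, and averaged detrended
#' Hann-windowed periodograms are formed.  The peak is located on power
#' smoothed with a moving mean.
#'
#' @param traj An `mtmd_trajectory` with at least 512 frames at a uniform
#'   sampling interval.
#' @param top The [topology()] of the system.
#' @param mode `"vib"`, `"rot"` or `"trans"`.
#' @param smooth_bins Moving-mean width (bins) for peak location.
#' @param min_frames Minimum number of frames required.
#' @return Object of class `spectral_result`: `frequencies` (ps^-1, 0 to
#'   Nyquist), `power`, `power_smooth`, `peak_frequency` (ps^-1).
#' @export
mode_filtered_spectrum <- function(traj, top, mode = c("vib", "rot", "trans"),
                                   smooth_bins = 5, min_frames = 512) {
  mode <- match.arg(mode)
  nf <- dim(traj$x)[3]
  if (nf < min_frames)
    stop(sprintf("need at least %d frames for spectral analysis, have %d",
                 min_frames, nf))
  sig <- .mode_signals(traj, top, mode)     # nf x n_signals matrix
  dt_ps <- .frame_dt_ps(traj)
  # second time derivative, central differences
  acc <- (sig[-(1:2), , drop = FALSE] - 2 * sig[-c(1, nrow(sig)), , drop = FALSE] +
            sig[1:(nrow(sig) - 2), , drop = FALSE]) / dt_ps^2
  n <- nrow(acc)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))   # Hann
  tgrid <- seq_len(n)
  pow <- NULL
  for (j in seq_len(ncol(acc))) {
    y <- acc[, j]
    fit <- stats::lm.fit(cbind(1, tgrid), y)              # detrend
    y <- fit$residuals * win
    p <- Mod(stats::fft(y))^2
    pow <- if (is.null(pow)) p else pow + p
  }
  pow <- pow / ncol(acc)
  nhalf <- floor(n / 2) + 1
  freq <- (seq_len(nhalf) - 1) / (n * dt_ps)
  pow <- pow[seq_len(nhalf)]
  ps <- .moving_mean(pow, smooth_bins)
  skip <- max(2L, smooth_bins %/% 2 + 1L)   # exclude the zero-frequency bins
  peak <- freq[skip - 1 + which.max(ps[skip:length(ps)])]
  structure(list(frequencies = freq, power = pow, power_smooth = ps,
                 peak_frequency = peak, mode = mode),
            class = "spectral_result")
}

.moving_mean <- function(x, k) {
  if (k <= 1) return(x)
  v <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  v[is.na(v)] <- x[is.na(v)]
  v
}

.mode_signals <- function(traj, top, mode) {
  nf <- dim(traj$x)[3]
  mol_atoms <- .molecule_atoms(top)
  if (mode == "trans") {
    out <- matrix(0, nf, 3 * length(mol_atoms))
    for (m in seq_along(mol_atoms)) {
      atoms <- mol_atoms[[m]]
      w <- top$masses[atoms] / sum(top$masses[atoms])
      for (k in seq_len(nf)) {
        out[k, (3 * m - 2):(3 * m)] <-
          as.numeric(matrix(traj$x[, atoms, k], nrow = 3) %*% w)
      }
    }
    return(out)
  }
  if (mode == "vib") {
    bonds <- top$bonds
    if (nrow(bonds) == 0) stop("no bonds for vibrational signal")
    out <- matrix(0, nf, nrow(bonds))
    for (k in seq_len(nf)) {
      d <- traj$x[, bonds[, 2], k] - traj$x[, bonds[, 1], k]
      out[k, ] <- sqrt(colSums(matrix(d, nrow = 3)^2))
    }
    return(out)
  }
  # rotation: cosine of the molecular-axis angle to the laboratory z axis
  sizes <- lengths(mol_atoms)
  if (any(sizes != 2))
    stop("rotational signal is defined for diatomic molecules")
  out <- matrix(0, nf, length(mol_atoms))
  for (m in seq_along(mol_atoms)) {
    atoms <- mol_atoms[[m]]
    for (k in seq_len(nf)) {
      d <- traj$x[, atoms[2], k] - traj$x[, atoms[1], k]
      out[k, m] <- d[3] / sqrt(sum(d^2))
    }
  }
  out
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("%s spectrum: peak at %.3f ps^-1 (%d bins to Nyquist %.2f)\n",
              x$mode, x$peak_frequency, length(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

#' Vibrational frequencies from the mass-weighted Hessian
#'
#' Computes the eigenvalues \eqn{\omega_j^2} of
#' \eqn{M^{-1/2} H M^{-1/2}} (identical to the generalized eigenvalues of
#' `(H, M)`), the highest frequency, and the time-step rule of one tenth of
#' the fastest oscillation period.
#'
#' @param H Symmetric Cartesian Hessian (eV/A^2).
#' @param M Positive definite mass matrix (u), same dimension.
#' @return Object of class `frequency_report`: `omega` (rad/ps, ascending,
#'   zero for negative eigenvalues), `n_imaginary` (count of negative
#'   eigenvalues beyond tolerance), `f_max` (ps^-1) and `dt_rule` (fs).
#' @export
mass_weighted_frequencies <- function(H, M) {
  H <- (H + t(H)) / 2
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(em$values <= 0)) stop("mass matrix must be positive definite")
  Mih <- em$vectors %*% ((1 / sqrt(em$values)) * t(em$vectors))
  S <- Mih %*% H %*% Mih
  w2 <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(abs(w2), 1e-300)
  n_imag <- sum(w2 < -tol)
  omega_int <- sqrt(pmax(w2, 0))                 # rad per internal time unit
  omega <- sort(omega_int) * 1000 / .TAU_FS      # rad/ps
  f_max <- max(omega) / (2 * pi)                 # ps^-1
  dt_rule <- if (f_max > 0) (1000 / f_max) / 10 else Inf   # fs
  structure(list(omega = omega, n_imaginary = n_imag, f_max = f_max,
                 dt_rule = dt_rule),
            class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  cat(sprintf(paste0("frequency report: f_max = %.2f ps^-1 (%d modes, %d ",
                     "imaginary), dt rule = %.3f fs\n"),
              x$f_max, length(x$omega), x$n_imaginary, x$dt_rule))
  invisible(x)
}

#' Maximum numerically stable time step on a grid
#'
#' Runs the supplied simulation at each candidate time step and accepts a
#' step when the run completes with all solvers converging and the
#' conserved quantity stays bounded: the full-horizon excursion must not
#' exceed the baseline band by more than an absolute criterion (default
#' 1 meV/atom).  The baseline band is the excursion over the initial
#' `baseline_fraction` of the run; it captures the bounded discretization
#' oscillation of the symplectic integrator (which scales as dt^2 away
#' from the stability edge), so the criterion rejects secular drift,
#' resonant growth and energy jumps rather than the oscillation itself.
#'
#' @param runner Function `(dt_fs, n_steps)` returning an
#'   `mtmd_trajectory`; it must rebuild the same initial conditions on
#'   every call.
#' @param dt_grid Ascending candidate time steps (fs).
#' @param horizon_steps Steps each candidate must survive.
#' @param criterion_meV_per_atom Allowed excursion beyond the baseline
#'   band (meV/atom).
#' @param baseline_fraction Fraction of the run defining the baseline
#'   band.
#' @return List with `dt_max` (fs; `NA` if none passed) and `detail` (data
#'   frame per candidate).
#' @export
max_stable_dt <- function(runner, dt_grid, horizon_steps,
                          criterion_meV_per_atom = 1,
                          baseline_fraction = 0.2) {
  stopifnot(!is.unsorted(dt_grid))
  rows <- list()
  for (dt in dt_grid) {
    tr <- runner(dt, horizon_steps)
    n_at <- dim(tr$x)[2]
    if (tr$status == "ok") {
      exc <- abs(tr$conserved - tr$conserved[1]) / n_at
      nb <- max(2L, ceiling(baseline_fraction * length(exc)))
      base_band <- max(exc[seq_len(nb)])
      band <- max(exc)
    } else {
      base_band <- band <- Inf
    }
    allowed <- base_band + criterion_meV_per_atom * 1e-3
    ok <- tr$status == "ok" && is.finite(band) && band <= allowed
    rows[[length(rows) + 1]] <-
      data.frame(dt = dt, stable = ok, band_eV_per_atom = band,
                 baseline_eV_per_atom = base_band,
                 allowed_eV_per_atom = allowed, status = tr$status)
  }
  detail <- do.call(rbind, rows)
  passing <- detail$dt[detail$stable]
  list(dt_max = if (length(passing)) max(passing) else NA_real_,
       detail = detail)
}

#' Radial distribution function
#'
#' Ideal-gas-normalized pair-distance histogram averaged over frames,
#' using the minimum-image convention with the per-frame cell.
#'
#' @param traj An `mtmd_trajectory`.
#' @param species Character vector of length 2 selecting the element pair
#'   (e.g. `c("N", "N")`); `NULL` uses all atoms.
#' @param r_max Histogram range (A); must stay below half the minimum cell
#'   width.
#' @param n_bins Number of bins.
#' @param frame_stride Use every `frame_stride`-th frame.
#' @return Data frame with `r` (bin centers, A) and `g`.
#' @export
rdf <- function(traj, species = NULL, r_max, n_bins = 100, frame_stride = 1) {
  nf <- dim(traj$x)[3]
  frames <- seq(1, nf, by = frame_stride)
  elements <- traj$elements
  if (is.null(species)) species <- c(NA, NA)
  selA <- if (is.na(species[1])) seq_along(elements) else
    which(elements == species[1])
  selB <- if (is.na(species[2])) seq_along(elements) else
    which(elements == species[2])
  same <- identical(selA, selB)
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  norm_acc <- 0
  for (k in frames) {
    h <- traj$h[, , k]
    if (r_max >= .min_cell_width(h) / 2)
      stop("r_max must be below half the minimum cell width")
    hin <- solve(h)
    xk <- traj$x[, , k]
    sA <- hin %*% xk[, selA, drop = FALSE]
    sB <- hin %*% xk[, selB, drop = FALSE]
    if (same) {
      n <- length(selA)
      pr <- utils::combn(n, 2)
      ds <- sA[, pr[1, ], drop = FALSE] - sA[, pr[2, ], drop = FALSE]
      npair <- n * (n - 1) / 2
    } else {
      ia <- rep(seq_along(selA), times = length(selB))
      ib <- rep(seq_along(selB), each = length(selA))
      ds <- sA[, ia, drop = FALSE] - sB[, ib, drop = FALSE]
      npair <- length(selA) * length(selB)
    }
    ds <- ds - round(ds)
    d <- sqrt(colSums((h %*% ds)^2))
    counts <- counts + graphics::hist(d[d < r_max], breaks = breaks,
                                      plot = FALSE)$counts
    norm_acc <- norm_acc + npair / det(h)
  }
  rc <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dr <- diff(breaks)
  shell <- 4 * pi * rc^2 * dr
  dens <- norm_acc          # sum over frames of n_pairs / V
  g <- counts / (shell * dens)
  data.frame(r = rc, g = g)
}

#' Self-diffusion coefficient from the mean squared displacement
#'
#' Computes the origin-averaged MSD of the selected atoms from unwrapped
#' positions and fits `msd = 6 D t + intercept` by least squares over the
#' chosen lag window.  A log-log slope near 2 marks ballistic motion, for
#' which the linear fit is flagged as unreliable.
#'
#' @param traj An `mtmd_trajectory` (positions are stored unwrapped).
#' @param species Element symbol selecting atoms (`NULL` = all).
#' @param fit_window Fractions of the maximum lag used in the fit.
#' @param origin_stride Stride between time origins (frames).
#' @return List with `D` (A^2/ps), `intercept`, `msd` data frame,
#'   `loglog_slope` and `ballistic` flag.
#' @export
diffusion_fit <- function(traj, species = NULL, fit_window = c(0.1, 0.5),
                          origin_stride = 10) {
  nf <- dim(traj$x)[3]
  sel <- if (is.null(species)) seq_along(traj$elements) else
    which(traj$elements == species)
  if (length(sel) == 0) stop("no atoms match the requested species")
  dt_ps <- .frame_dt_ps(traj)
  max_lag <- nf - 1
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  cnt <- numeric(max_lag)
  origins <- seq(1, nf - 1, by = origin_stride)
  X <- traj$x[, sel, , drop = FALSE]
  for (t0 in origins) {
    lag_avail <- seq_len(nf - t0)
    d <- X[, , t0 + lag_avail, drop = FALSE] -
      array(X[, , t0], c(3, length(sel), length(lag_avail)))
    msd_part <- apply(d^2, 3, sum) / length(sel)
    msd[lag_avail] <- msd[lag_avail] + msd_part
    cnt[lag_avail] <- cnt[lag_avail] + 1
  }
  msd <- msd / cnt
  tt <- lags * dt_ps
  win <- tt >= fit_window[1] * max(tt) & tt <= fit_window[2] * max(tt)
  fit <- stats::lm(msd[win] ~ tt[win])
  slope <- unname(stats::coef(fit)[2])
  pos <- win & msd > 0
  loglog_slope <- if (sum(pos) >= 3) {
    unname(stats::coef(stats::lm(log(msd[pos]) ~ log(tt[pos])))[2])
  } else NA_real_
  list(D = slope / 6, intercept = unname(stats::coef(fit)[1]),
       msd = data.frame(t = tt, msd = msd),
       loglog_slope = loglog_slope,
       ballistic = is.finite(loglog_slope) && loglog_slope > 1.6)
}

#' Detect orientational (polymorph) transitions between two molecules
#'
#' The main axis of each molecule is the direction between the centroids
#' of two atom groups.  A transition event is recorded when the rolling
#' trailing mean (over `window` frames) of the inter-axis angle crosses
#' `angle_thresh` upward.  Events are excluded when an intramolecular kink
#' (angle between the two kink axes of one molecule) exceeds `kink_thresh`
#' at the crossing, or when a user-supplied cell-shape predicate fails.
#'
#' @param traj An `mtmd_trajectory`.
#' @param axes_spec List of two molecule specifications, each a list with
#'   `axis = list(groupA, groupB)` (atom index vectors whose centroids
#'   define the main axis) and optionally
#'   `kink = list(list(gA, gB), list(gA, gB))` defining two intramolecular
#'   axes.
#' @param window Rolling-average window in frames (default 100).
#' @param angle_thresh Event threshold in degrees (default 80).
#' @param kink_thresh Kink exclusion threshold in degrees (default 30).
#' @param cell_predicate Optional function `h -> logical`; events with
#'   `FALSE` are excluded (reason `"cell"`).
#' @return Object of class `transition_report` with `events` and
#'   `excluded` data frames and the `angle` series (degrees).
#' @export
transition_detector <- function(traj, axes_spec, window = 100,
                                angle_thresh = 80, kink_thresh = 30,
                                cell_predicate = NULL) {
  stopifnot(length(axes_spec) == 2)
  nf <- dim(traj$x)[3]
  centroid <- function(xk, idx) rowMeans(xk[, idx, drop = FALSE])
  axis_of <- function(xk, spec) {
    a <- centroid(xk, spec[[2]]) - centroid(xk, spec[[1]])
    a / sqrt(sum(a^2))
  }
  line_angle <- function(u, v) {
    acos(min(1, abs(sum(u * v)))) * 180 / pi
  }
  angle <- numeric(nf)
  kink <- matrix(0, nf, 2)
  for (k in seq_len(nf)) {
    xk <- traj$x[, , k]
    a1 <- axis_of(xk, axes_spec[[1]]$axis)
    a2 <- axis_of(xk, axes_spec[[2]]$axis)
    angle[k] <- line_angle(a1, a2)
    for (m in 1:2) {
      ks <- axes_spec[[m]]$kink
      if (!is.null(ks)) {
        u <- axis_of(xk, ks[[1]]); v <- axis_of(xk, ks[[2]])
        kink[k, m] <- line_angle(u, v)
      }
    }
  }
  roll <- stats::filter(angle, rep(1 / window, window), sides = 1)
  roll <- as.numeric(roll)
  events <- excluded <- list()
  for (k in seq(2, nf)) {
    if (!is.na(roll[k]) && !is.na(roll[k - 1]) &&
        roll[k - 1] <= angle_thresh && roll[k] > angle_thresh) {
      kk <- max(kink[k, ])
      cell_ok <- if (is.null(cell_predicate)) TRUE else
        isTRUE(cell_predicate(traj$h[, , k]))
      if (kk > kink_thresh) {
        excluded[[length(excluded) + 1]] <-
          data.frame(step = k, angle = roll[k], reason = "kink")
      } else if (!cell_ok) {
        excluded[[length(excluded) + 1]] <-
          data.frame(step = k, angle = roll[k], reason = "cell")
      } else {
        events[[length(events) + 1]] <- data.frame(step = k, angle = roll[k])
      }
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  structure(list(
    events = bind(events, data.frame(step = integer(0), angle = numeric(0))),
    excluded = bind(excluded, data.frame(step = integer(0),
                                         angle = numeric(0),
                                         reason = character(0))),
    angle = angle, rolling = roll),
    class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("transition report: %d events, %d excluded\n",
              nrow(x$events), nrow(x$excluded)))
  invisible(x)
}
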