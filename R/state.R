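# Dynamical state of a variable-cell system: fractional coordinates s,
# cell matrix h (columns = lattice vectors), scaled momenta ps and cell
# momenta ph.  Cartesian positions are R = h s.

#' Construct a system state
#'
#' @param s 3 x N fractional coordinates (dimensionless).  Molecules should
#'   be whole (bonded atoms not split across periodic images); coordinates
#'   are never wrapped during dynamics.
#' @param h 3 x 3 cell matrix (Angstrom), columns are lattice vectors,
#'   `det(h) > 0`.
#' @param ps 3 x N scaled momenta (conjugate to `s`; internal units).
#' @param ph 3 x 3 cell momenta.
#' @param t Elapsed time in fs.
#' @return Object of class `mtmd_state`.
#' @export
system_state <- function(s, h, ps = NULL, ph = NULL, t = 0) {
  s <- as.matrix(s); h <- as.matrix(h)
  stopifnot(nrow(s) == 3, all(dim(h) == c(3, 3)))
  if (is.null(ps)) ps <- matrix(0, 3, ncol(s))
  if (is.null(ph)) ph <- matrix(0, 3, 3)
  ps <- as.matrix(ps); ph <- as.matrix(ph)
  if (!all(is.finite(s)) || !all(is.finite(h)) || !all(is.finite(ps)) ||
      !all(is.finite(ph)))
    stop("non-finite entries in system state")
  if (det(h) <= 0) stop("cell matrix must have positive determinant")
  structure(list(s = s, h = h, ps = ps, ph = ph, t = t),
            class = "mtmd_state")
}

#' Cartesian positions of a state
#'
#' @param state An `mtmd_state`.
#' @return 3 x N matrix of Cartesian positions (Angstrom), `h %*% s`.
#' @export
positions <- function(state) state$h %*% state$s

#' @export
print.mtmd_state <- function(x, ...) {
  cat(sprintf("mtmd state: %d atoms, t = %.3f fs, det h = %.3f A^3\n",
              ncol(x$s), x$t, det(x$h)))
  invisible(x)
}
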