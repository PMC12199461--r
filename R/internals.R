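# Evaluation of internal coordinates: values, Wilson B matrix (first
# derivatives w.r.t. Cartesian coordinates), per-coordinate second
# derivatives, and the thresholded pseudoinverse used in Hessian transforms.

#' Evaluate internal coordinates and their Cartesian derivatives
#'
#' Computes bond lengths (Angstrom), angles and dihedrals (radians) together
#' with the Wilson B matrix \eqn{B_{ij} = \partial q_i / \partial x_j} and,
#' optionally, the second-derivative matrices
#' \eqn{\partial^2 q_i / \partial x_j \partial x_k}.  Derivatives are exact
#' (forward-mode automatic differentiation), not finite differences.
#'
#' @param top An [topology()] object.
#' @param x 3 x N Cartesian positions (Angstrom), molecules whole.
#' @param second Compute second derivatives (default `TRUE`).
#' @param pinv Also compute the thresholded pseudoinverse of B.
#' @return Object of class `internal_evaluation` with `values`, `B`
#'   (n_internal x 3N), `B_pinv` (3N x n_internal, if requested) and `d2q`
#'   (list of compact per-coordinate matrices with attribute `vidx` giving
#'   the Cartesian variable indices).
#' @export
evaluate_internals <- function(top, x, second = TRUE, pinv = FALSE) {
  x <- as.matrix(x)
  n <- ncol(x)
  ct <- .coord_table(top)
  if (nrow(top$bonds) > 0) {
    bl <- sqrt(colSums((x[, top$bonds[, 2], drop = FALSE] -
                          x[, top$bonds[, 1], drop = FALSE])^2))
    if (any(bl < 1e-8)) stop("degenerate geometry: zero-length bond")
  }
  ev <- eval_internals_cpp(as.numeric(x), ct$type, ct$atoms - 1L, second)
  if (!all(is.finite(ev$values)) || !all(is.finite(ev$B)))
    stop("degenerate geometry: internal coordinate derivative undefined ",
         "(collinear angle or dihedral axis)")
  out <- list(values = ev$values, B = ev$B)
  if (second) {
    d2q <- ev$d2q
    for (i in seq_along(d2q)) attr(d2q[[i]], "vidx") <- ev$vidx[[i]] + 1L
    out$d2q <- d2q
  }
  if (pinv && length(ev$values) > 0) out$B_pinv <- thresholded_pinv(ev$B)
  out$type <- ct$type
  class(out) <- "internal_evaluation"
  out
}

# type codes (0 bond, 1 angle, 2 dihedral) and padded atom-index matrix
.coord_table <- function(top) {
  nb <- nrow(top$bonds); na <- nrow(top$angles); nd <- nrow(top$dihedrals)
  type <- rep(c(0L, 1L, 2L), c(nb, na, nd))
  atoms <- matrix(-1L, nb + na + nd, 4)
  if (nb) atoms[seq_len(nb), 1:2] <- top$bonds
  if (na) atoms[nb + seq_len(na), 1:3] <- top$angles
  if (nd) atoms[nb + na + seq_len(nd), 1:4] <- top$dihedrals
  list(type = type, atoms = atoms)
}

#' Moore-Penrose pseudoinverse with a relative singular-value threshold
#'
#' Singular values below `rel_tol` times the largest singular value are
#' treated as zero (default 1e-2, the threshold used in the redundant
#' internal-coordinate Hessian transforms).
#'
#' @param B Numeric matrix.
#' @param rel_tol Relative singular-value cutoff.
#' @return The pseudoinverse, with transposed shape of `B`.
#' @export
thresholded_pinv <- function(B, rel_tol = 1e-2) {
  B <- as.matrix(B)
  sv <- svd(B)
  smax <- if (length(sv$d) > 0) max(sv$d) else 0
  if (smax <= 0) stop("cannot invert an all-zero matrix")
  keep <- sv$d >= rel_tol * smax
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}
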