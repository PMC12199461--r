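# Topology: bond detection, enumeration of redundant internal coordinates
# (bonds, angles, dihedrals) and the molecule partition.

#' Detect covalent bonds from interatomic distances
#'
#' A bond is assigned to every atom pair whose (minimum-image) distance is
#' below `scale` times the sum of the two covalent radii.  Connected
#' components of the resulting bond graph define the molecules.
#'
#' @param x 3 x N matrix of Cartesian positions (Angstrom).
#' @param elements Character vector of N element symbols.
#' @param h Optional 3 x 3 cell matrix (columns = lattice vectors); when
#'   given, distances use the minimum-image convention in fractional space.
#' @param scale Dimensionless multiplier on the covalent-radius sum
#'   (default 1.2).
#' @return List with `bonds` (nb x 2 matrix of atom indices, each row
#'   `i < j`) and `molecule_ids` (integer vector of length N).
#' @export
detect_bonds <- function(x, elements, h = NULL, scale = 1.2) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == 3, all(is.finite(x)), scale > 0)
  n <- ncol(x)
  if (length(elements) != n) stop("length(elements) must match ncol(x)")
  radii <- covalent_radius(elements)
  if (!is.null(h)) {
    h <- as.matrix(h)
    if (abs(det(h)) < 1e-12) stop("cell matrix h is singular")
    s <- solve(h, x)
  }
  bonds <- matrix(integer(0), 0, 2)
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    if (is.null(h)) {
      d <- sqrt(colSums((x[, pairs[1, ], drop = FALSE] -
                           x[, pairs[2, ], drop = FALSE])^2))
    } else {
      ds <- s[, pairs[1, ], drop = FALSE] - s[, pairs[2, ], drop = FALSE]
      ds <- ds - round(ds)
      d <- sqrt(colSums((h %*% ds)^2))
    }
    crit <- scale * (radii[pairs[1, ]] + radii[pairs[2, ]])
    keep <- which(d < crit)
    bonds <- t(pairs[, keep, drop = FALSE])
  }
  list(bonds = bonds, molecule_ids = .connected_components(bonds, n))
}

.connected_components <- function(bonds, n) {
  comp <- integer(n)
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' Enumerate redundant internal coordinates from a bond list
#'
#' Builds all angles (paths of length two) and dihedrals (paths of length
#' three with four distinct atoms) that can be constructed from the bonds.
#' Angles whose reference value is within `linear_tol` of pi are excluded
#' when reference positions are supplied, because the Wilson B matrix is
#' singular there; dihedrals containing such an angle are excluded too.
#'
#' @param bonds nb x 2 matrix of atom indices.
#' @param n_atoms Total number of atoms.
#' @param include_angles,include_dihedrals Logical flags selecting the
#'   coordinate set (bonds only / bonds+angles / full).
#' @param x Optional 3 x N reference positions used for the near-linear
#'   angle filter.
#' @param linear_tol Exclusion tolerance (rad) around pi (default 1e-3).
#' @return List with `bonds`, `angles` (na x 3), `dihedrals` (nd x 4).
#' @export
enumerate_internals <- function(bonds, n_atoms, include_angles = TRUE,
                                include_dihedrals = TRUE, x = NULL,
                                linear_tol = 1e-3) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  nbrs <- vector("list", n_atoms)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  angles <- matrix(integer(0), 0, 3)
  dihedrals <- matrix(integer(0), 0, 4)
  if (include_angles) {
    out <- list()
    for (j in seq_len(n_atoms)) {
      nb <- sort(nbrs[[j]])
      if (length(nb) >= 2) {
        pr <- utils::combn(nb, 2)
        out[[length(out) + 1]] <- cbind(pr[1, ], j, pr[2, ])
      }
    }
    if (length(out) > 0) angles <- do.call(rbind, out)
    if (!is.null(x) && nrow(angles) > 0) {
      vals <- vapply(seq_len(nrow(angles)), function(a) {
        .angle_value(x[, angles[a, 1]], x[, angles[a, 2]], x[, angles[a, 3]])
      }, numeric(1))
      angles <- angles[vals < pi - linear_tol, , drop = FALSE]
    }
  }
  if (include_dihedrals && nrow(bonds) > 0) {
    linear_ok <- function(i, j, k) {
      if (is.null(x)) return(TRUE)
      .angle_value(x[, i], x[, j], x[, k]) < pi - linear_tol
    }
    out <- list()
    for (b in seq_len(nrow(bonds))) {
      j <- bonds[b, 1]; k <- bonds[b, 2]
      for (i in setdiff(nbrs[[j]], k)) {
        for (l in setdiff(nbrs[[k]], j)) {
          if (i == l) next
          if (!linear_ok(i, j, k) || !linear_ok(j, k, l)) next
          out[[length(out) + 1]] <- c(i, j, k, l)
        }
      }
    }
    if (length(out) > 0) dihedrals <- do.call(rbind, out)
  }
  storage.mode(angles) <- "integer"
  storage.mode(dihedrals) <- "integer"
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

.angle_value <- function(xi, xj, xk) {
  u <- xi - xj; v <- xk - xj
  cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cth)))
}

#' Construct a molecular topology
#'
#' @param elements Character vector of element symbols.
#' @param bonds,angles,dihedrals Internal coordinate index matrices
#'   (1-based atom indices; `NULL` for empty).
#' @param molecule_ids Integer molecule index per atom; derived from the
#'   bond graph when omitted.
#' @param masses Per-atom masses in u; taken from the bundled standard
#'   atomic weights when omitted.
#' @return An object of class `mtmd_topology`.
#' @export
topology <- function(elements, bonds, angles = NULL, dihedrals = NULL,
                     molecule_ids = NULL, masses = NULL) {
  n <- length(elements)
  bonds <- if (is.null(bonds)) matrix(integer(0), 0, 2) else
    matrix(as.integer(bonds), ncol = 2)
  angles <- if (is.null(angles)) matrix(integer(0), 0, 3) else
    matrix(as.integer(angles), ncol = 3)
  dihedrals <- if (is.null(dihedrals)) matrix(integer(0), 0, 4) else
    matrix(as.integer(dihedrals), ncol = 4)
  if (is.null(molecule_ids)) molecule_ids <- .connected_components(bonds, n)
  if (is.null(masses)) masses <- atomic_mass(elements)
  obj <- structure(
    list(elements = elements, masses = masses,
         molecule_ids = as.integer(molecule_ids),
         bonds = bonds, angles = angles, dihedrals = dihedrals),
    class = "mtmd_topology")
  .validate_topology(obj)
  obj
}

.validate_topology <- function(top) {
  n <- length(top$elements)
  stopifnot(length(top$masses) == n, length(top$molecule_ids) == n,
            all(top$masses > 0))
  mid <- top$molecule_ids
  if (any(mid < 1L)) stop("molecule partition must cover all atoms")
  check_same_mol <- function(mat, what) {
    if (nrow(mat) == 0) return(invisible())
    if (any(mat < 1 | mat > n)) stop(what, " references atoms out of range")
    ids <- matrix(mid[mat], nrow(mat))
    if (any(apply(ids, 1, function(r) length(unique(r)) != 1)))
      stop(what, " must not cross molecules")
  }
  check_same_mol(top$bonds, "bonds")
  check_same_mol(top$angles, "angles")
  check_same_mol(top$dihedrals, "dihedrals")
  if (nrow(top$bonds) > 0) {
    key <- apply(t(apply(top$bonds, 1, sort)), 1, paste, collapse = "-")
    if (anyDuplicated(key)) stop("duplicate bonds")
  }
  invisible(top)
}

#' Build a topology from positions by bond detection and enumeration
#'
#' @inheritParams detect_bonds
#' @inheritParams enumerate_internals
#' @return An `mtmd_topology`.
#' @export
build_topology <- function(x, elements, h = NULL, scale = 1.2,
                           include_angles = TRUE, include_dihedrals = TRUE,
                           linear_tol = 1e-3) {
  det <- detect_bonds(x, elements, h, scale)
  ic <- enumerate_internals(det$bonds, length(elements),
                            include_angles, include_dihedrals,
                            x = x, linear_tol = linear_tol)
  topology(elements, ic$bonds, ic$angles, ic$dihedrals,
           molecule_ids = det$molecule_ids)
}

#' @export
print.mtmd_topology <- function(x, ...) {
  cat(sprintf("mtmd topology: %d atoms, %d molecules\n",
              length(x$elements), max(x$molecule_ids, 0L)))
  cat(sprintf("  %d bonds, %d angles, %d dihedrals\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  invisible(x)
}

#' Tabulate internal coordinates with their current values
#'
#' @param top An `mtmd_topology`.
#' @param x 3 x N Cartesian positions (Angstrom).
#' @return Data frame with columns `type`, `atoms` (dash-separated indices)
#'   and `value` (Angstrom for bonds, radians for angles/dihedrals).
#' @export
internal_coord_report <- function(top, x) {
  ev <- evaluate_internals(top, x, second = FALSE)
  n_b <- nrow(top$bonds); n_a <- nrow(top$angles); n_d <- nrow(top$dihedrals)
  type <- rep(c("bond", "angle", "dihedral"), c(n_b, n_a, n_d))
  fmt <- function(m) apply(m, 1, paste, collapse = "-")
  atoms <- c(if (n_b) fmt(top$bonds), if (n_a) fmt(top$angles),
             if (n_d) fmt(top$dihedrals))
  data.frame(type = type, atoms = atoms, value = ev$values,
             stringsAsFactors = FALSE)
}

# atom indices per molecule, in increasing order
.molecule_atoms <- function(top) {
  split(seq_along(top$molecule_ids), top$molecule_ids)
}

#' Shift fractional coordinates so each molecule is connected (whole)
#'
#' Walks the bond graph of each molecule and translates atoms by lattice
#' vectors so every bonded pair is a minimum image of itself.  Internal
#' coordinates are evaluated on unwrapped Cartesian positions thereafter.
#'
#' @param s 3 x N fractional coordinates.
#' @param top An `mtmd_topology`.
#' @return Adjusted 3 x N fractional coordinates.
#' @export
make_molecules_whole <- function(s, top) {
  n <- ncol(s)
  adj <- vector("list", n)
  if (nrow(top$bonds) > 0) {
    for (b in seq_len(nrow(top$bonds))) {
      i <- top$bonds[b, 1]; j <- top$bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(n)
  for (start in seq_len(n)) {
    if (seen[start]) next
    seen[start] <- TRUE
    queue <- start
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          s[, w] <- s[, w] - round(s[, w] - s[, v])
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  s
}
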