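# Bundled element data: single-bond covalent radii (Cordero et al. 2008
# consensus values, Angstrom) and standard atomic masses (u).

.covalent_radii <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Fe = 1.32,
  Cu = 1.32, Zn = 1.22, Br = 1.20, Kr = 1.16, I = 1.39, Xe = 1.40
)

.atomic_masses <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797, Na = 22.98976928,
  Mg = 24.305, Al = 26.9815385, Si = 28.085, P = 30.973761998, S = 32.06,
  Cl = 35.45, Ar = 39.948, K = 39.0983, Ca = 40.078, Fe = 55.845,
  Cu = 63.546, Zn = 65.38, Br = 79.904, Kr = 83.798, I = 126.90447,
  Xe = 131.293
)

.element_lookup <- function(table, elements, what) {
  unknown <- setdiff(unique(elements), names(table))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s) for ", what, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(table[elements])
}

#' Covalent radii of chemical elements
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of single-bond covalent radii in Angstrom.
#' @export
covalent_radius <- function(elements) {
  .element_lookup(.covalent_radii, elements, "covalent radius")
}

#' Standard atomic masses
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of atomic masses in u.
#' @export
atomic_mass <- function(elements) {
  .element_lookup(.atomic_masses, elements, "atomic mass")
}
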