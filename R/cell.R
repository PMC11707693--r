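#' Unit cell and basis transforms
#'
#' Minimal triclinic cell support: fractional <-> Cartesian
#' orthogonalization, the reciprocal basis, d-spacings and reciprocal
#' vectors for hkl triples, and the reciprocal-basis <-> Cartesian ADP
#' conversion used at the CIF boundary.
#'
#' @name unit-cell
NULL

#' Construct a unit cell
#'
#' @param a,b,c cell edges (angstrom)
#' @param alpha,beta,gamma cell angles (degrees)
#' @return a `unit_cell` object with the orthogonalization matrix `A`
#'   (fractional -> Cartesian, angstrom), its inverse `Ainv`, the
#'   reciprocal basis `B = t(Ainv)` (columns a*, b*, c* in angstrom^-1)
#'   and `volume` (angstrom^3)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("cell angles do not define a positive volume")
  vol <- a * b * c * sqrt(vfac)
  # standard orthogonalization (a along x, b in xy plane)
  A <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, vol / (a * b * sg)), 3, 3, byrow = TRUE)
  Ainv <- solve(A)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, A = A, Ainv = Ainv, B = t(Ainv),
                 volume = vol),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%g b=%g c=%g  alpha=%g beta=%g gamma=%g  V=%.4f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional to Cartesian coordinates
#' @param cell a [unit_cell()]
#' @param frac n x 3 matrix or length-3 vector of fractional coordinates
#' @return n x 3 Cartesian coordinates (angstrom)
#' @export
frac_to_cart <- function(cell, frac) {
  frac <- .as_point_matrix(frac)
  frac %*% t(cell$A)
}

#' Cartesian to fractional coordinates
#' @param cell a [unit_cell()]
#' @param cart n x 3 matrix or length-3 vector (angstrom)
#' @return n x 3 fractional coordinates
#' @export
cart_to_frac <- function(cell, cart) {
  cart <- .as_point_matrix(cart)
  cart %*% t(cell$Ainv)
}

#' Cartesian reciprocal vectors for hkl triples
#' @param cell a [unit_cell()]
#' @param hkl n x 3 integer matrix
#' @return n x 3 matrix of reciprocal vectors (angstrom^-1)
#' @export
hkl_to_cart <- function(cell, hkl) {
  hkl <- .as_point_matrix(hkl)
  hkl %*% cell$B
}

#' d-spacings for hkl triples
#' @param cell a [unit_cell()]
#' @param hkl n x 3 integer matrix
#' @return d-spacings (angstrom)
#' @export
d_spacing <- function(cell, hkl) {
  s <- hkl_to_cart(cell, hkl)
  1 / sqrt(rowSums(s^2))
}

#' Convert a CIF-convention aniso U to Cartesian
#'
#' CIF stores U_ano with respect to the reciprocal basis:
#' U_cart = (A N) U_cif (A N)' with N = diag(a*, b*, c*).
#'
#' @param cell a [unit_cell()]
#' @param U_cif 3x3 matrix (or length-6 U11,U22,U33,U12,U13,U23)
#' @return 3x3 Cartesian U (angstrom^2)
#' @export
u_cif_to_cart <- function(cell, U_cif) {
  U_cif <- .as_U(adp_tensor(U_cif))
  N <- diag(sqrt(rowSums(cell$B^2)))  # |a*|, |b*|, |c*|
  M <- cell$A %*% N
  M %*% U_cif %*% t(M)
}

#' Convert a Cartesian U to the CIF reciprocal-basis convention
#' @param cell a [unit_cell()]
#' @param U_cart 3x3 Cartesian U (angstrom^2)
#' @return 3x3 U in the CIF convention
#' @export
u_cart_to_cif <- function(cell, U_cart) {
  U_cart <- .as_U(adp_tensor(U_cart))
  N <- diag(sqrt(rowSums(cell$B^2)))
  Minv <- solve(cell$A %*% N)
  Minv %*% U_cart %*% t(Minv)
}
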