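#' Spherical atomic densities and toy molecular densities
#'
#' The promolecule building block is a spherically averaged isolated-atom
#' density rho0_A(r). The shipped default is a single-zeta Slater 1s form,
#' rho(r) = N_e * (zeta^3/pi) * exp(-2*zeta*r) in atomic units (r in bohr,
#' density in e/bohr^3), which integrates exactly to `electron_count`
#' electrons. The partition algebra never looks inside the density object,
#' so any non-negative normalized radial profile can be plugged in.
#'
#' @name radial-densities
NULL

# packaged per-element zeta defaults (inst/extdata/slater_zeta.txt)
.zeta_table_cache <- new.env(parent = emptyenv())

#' Default Slater screening exponents per element
#'
#' Reads the packaged plain-text key-value table of per-element single-zeta
#' exponents (bohr^-1). Values are toy defaults chosen to give hydrogenic
#' tails of roughly valence-like diffuseness; they are configuration, not
#' physical constants.
#'
#' @param path optional path to an alternative key-value table
#'   (lines of "element zeta"; `#` comments allowed).
#' @return named numeric vector of zeta values
#' @export
slater_zeta_defaults <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.zeta_table_cache$tab)) return(.zeta_table_cache$tab)
    path <- system.file("extdata", "slater_zeta.txt", package = "exphar")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  tab <- vapply(parts, function(p) as.numeric(p[[2]]), numeric(1))
  names(tab) <- vapply(parts, `[[`, character(1), 1L)
  .zeta_table_cache$tab <- tab
  tab
}

#' Default valence (bond-orbital) exponents per element
#'
#' Packaged key-value table of the single-zeta exponents used for the
#' two-electron bond orbitals of the bonding total-density model.
#'
#' @param path optional alternative table path
#' @return named numeric vector of zeta values
#' @export
slater_valence_zeta_defaults <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.zeta_table_cache$vtab)) return(.zeta_table_cache$vtab)
    path <- system.file("extdata", "slater_valence_zeta.txt",
                        package = "exphar")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  tab <- vapply(parts, function(p) as.numeric(p[[2]]), numeric(1))
  names(tab) <- vapply(parts, `[[`, character(1), 1L)
  .zeta_table_cache$vtab <- tab
  tab
}

#' Construct a Slater 1s radial density
#'
#' @param element element label (used to look up the default zeta and, by
#'   default, the electron count)
#' @param zeta screening exponent in bohr^-1; default from
#'   [slater_zeta_defaults()]
#' @param electron_count number of electrons the density integrates to;
#'   defaults to the element's toy nuclear charge from [element_z()]
#' @return a `radial_density` object with fields `element_label`,
#'   `electron_count`, `zeta`, `evaluate` (density at r, bohr in, e/bohr^3
#'   out) and `unit_system = "bohr"`
#' @examples
#' h <- slater_density("H")
#' h$evaluate(0)        # 1/pi
#' @export
slater_density <- function(element, zeta = NULL, electron_count = NULL) {
  if (is.null(zeta)) {
    tab <- slater_zeta_defaults()
    if (!element %in% names(tab))
      stop("no default zeta for element '", element, "'; pass `zeta`")
    zeta <- tab[[element]]
  }
  if (!is.numeric(zeta) || zeta <= 0) stop("zeta must be > 0")
  if (is.null(electron_count)) electron_count <- element_z(element)
  if (electron_count < 0) stop("electron_count must be >= 0")
  force(zeta); force(electron_count)
  f <- function(r) {
    if (any(r < 0)) stop("radius must be non-negative")
    electron_count * (zeta^3 / pi) * exp(-2 * zeta * r)
  }
  structure(
    list(element_label = element, electron_count = electron_count,
         zeta = zeta, evaluate = f, unit_system = "bohr"),
    class = "radial_density")
}

#' @export
print.radial_density <- function(x, ...) {
  cat(sprintf("<radial_density> %s: %g e, zeta = %g bohr^-1 (Slater 1s)\n",
              x$element_label, x$electron_count, x$zeta))
  invisible(x)
}

#' Toy nuclear charges
#'
#' Z values for the handful of element labels the toy models use. The
#' pseudo-element "X" is the generic heavy bonding partner used by the
#' synthetic-crystal templates.
#' @param element element label
#' @return integer nuclear charge
#' @export
element_z <- function(element) {
  z <- c(H = 1, He = 2, C = 6, N = 7, O = 8, X = 7)
  if (!element %in% names(z))
    stop("no toy Z for element '", element, "'; pass electron_count explicitly")
  unname(z[[element]])
}

#' Evaluate a single-zeta Slater 1s density
#'
#' Convenience scalar form of the shipped isolated-atom model:
#' `electron_count * (zeta^3/pi) * exp(-2 zeta r)` in atomic units.
#'
#' @param element element label (sets default electron count)
#' @param zeta screening exponent (bohr^-1), > 0
#' @param r radius (bohr), >= 0; vectorized
#' @param electron_count electrons; defaults to Z(element)
#' @return density in e/bohr^3
#' @export
radial_density <- function(element, zeta, r, electron_count = NULL) {
  slater_density(element, zeta = zeta, electron_count = electron_count)$evaluate(r)
}

#' Place radial densities at sites
#'
#' Builds the site list that defines a promolecule: each entry pairs a
#' `radial_density` with a Cartesian position in bohr.
#'
#' @param densities list of `radial_density` objects
#' @param positions numeric matrix, one row per site, columns x,y,z (bohr)
#' @return list of placed sites (class `promolecule_sites`)
#' @export
place_sites <- function(densities, positions) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (length(densities) != nrow(positions))
    stop("need one position per density")
  if (length(densities) == 0L) stop("at least one site is required")
  sites <- lapply(seq_along(densities), function(i) {
    list(density = densities[[i]], position = positions[i, ])
  })
  class(sites) <- "promolecule_sites"
  sites
}

#' Promolecule density at points
#'
#' Sum of isolated-atom densities placed at the nuclear positions:
#' rho_pro(r) = sum_A rho0_A(|r - x_A|).
#'
#' @param sites placed sites from [place_sites()]
#' @param points numeric matrix (n x 3) of Cartesian positions in bohr, or a
#'   length-3 vector
#' @return numeric vector of densities (e/bohr^3)
#' @export
promolecule_density <- function(sites, points) {
  m <- .site_density_matrix(sites, points)
  rowSums(m)
}

# n_points x n_sites matrix of per-site isolated-atom densities
.site_density_matrix <- function(sites, points) {
  if (length(sites) == 0L) stop("empty site list")
  points <- .as_point_matrix(points)
  m <- vapply(sites, function(s) {
    d <- sqrt((points[, 1] - s$position[1])^2 +
              (points[, 2] - s$position[2])^2 +
              (points[, 3] - s$position[3])^2)
    s$density$evaluate(d)
  }, numeric(nrow(points)))
  matrix(m, nrow = nrow(points), ncol = length(sites))
}

.as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must have 3 columns")
  points
}

#' One-electron two-centre toy molecular density
#'
#' Density of the simplest two-centre bond model: a single electron in
#' psi = N (phi_A + phi_B) with phi_* hydrogenic 1s orbitals (zeta = 1)
#' on nuclei separated by `R` bohr, N^2 = 1/(2(1+S)) and
#' S = exp(-R)(1 + R + R^2/3) the closed-form 1s-1s overlap.
#' The density integrates to exactly one electron.
#'
#' @param R internuclear separation (bohr), > 0. Nuclei sit at
#'   (-R/2, 0, 0) and (+R/2, 0, 0).
#' @param points n x 3 matrix (or length-3 vector) of positions in bohr
#' @return density values (e/bohr^3)
#' @export
toy_two_center_density <- function(R, points) {
  if (!is.numeric(R) || R <= 0) stop("R must be > 0")
  points <- .as_point_matrix(points)
  S <- slater_overlap_1s(R)
  N2 <- 1 / (2 * (1 + S))
  rA <- sqrt((points[, 1] + R / 2)^2 + points[, 2]^2 + points[, 3]^2)
  rB <- sqrt((points[, 1] - R / 2)^2 + points[, 2]^2 + points[, 3]^2)
  phiA <- exp(-rA) / sqrt(pi)
  phiB <- exp(-rB) / sqrt(pi)
  N2 * (phiA + phiB)^2
}

#' Closed-form 1s-1s overlap integral
#'
#' S(R) = exp(-R) (1 + R + R^2/3) for two unit-zeta hydrogenic 1s orbitals
#' R bohr apart.
#' @param R separation in bohr
#' @return overlap integral (dimensionless)
#' @export
slater_overlap_1s <- function(R) exp(-R) * (1 + R + R^2 / 3)

#' Two-centre bond-pair density
#'
#' Density of an electron pair in the bonding LCAO orbital
#' sigma = N (phi_A + phi_B), with phi_A, phi_B single-zeta 1s orbitals
#' (exponents `zeta_a`, `zeta_b`) on nuclei `pos_a`, `pos_b` (bohr) and
#' N^2 = 1/(2 (1 + S_AB)). The heteronuclear 1s-1s overlap S_AB is
#' evaluated once by atom-centred quadrature (symmetrized over the two
#' centres); the density integrates to `n_electrons` to the same
#' accuracy.
#'
#' @param pos_a,pos_b nuclear positions (bohr)
#' @param zeta_a,zeta_b orbital exponents (bohr^-1)
#' @param n_electrons electrons in the orbital (default 2)
#' @return list with `evaluate` (points -> density), `electron_count`,
#'   `overlap` (the computed S_AB)
#' @export
bond_pair_density <- function(pos_a, pos_b, zeta_a = 1, zeta_b = 1,
                              n_electrons = 2) {
  pos_a <- as.numeric(pos_a); pos_b <- as.numeric(pos_b)
  phi <- function(points, pos, zeta) {
    d <- sqrt((points[, 1] - pos[1])^2 + (points[, 2] - pos[2])^2 +
              (points[, 3] - pos[3])^2)
    sqrt(zeta^3 / pi) * exp(-zeta * d)
  }
  prod_f <- function(points) phi(points, pos_a, zeta_a) * phi(points, pos_b, zeta_b)
  sg <- sphere_grid(974); rg <- radial_grid(100)
  S <- mean(c(atom_centered_integrate(prod_f, pos_a, sg, rg),
              atom_centered_integrate(prod_f, pos_b, sg, rg)))
  N2 <- 1 / (2 * (1 + S))
  evaluate <- function(points) {
    points <- .as_point_matrix(points)
    n_electrons * N2 * (phi(points, pos_a, zeta_a) +
                        phi(points, pos_b, zeta_b))^2
  }
  list(evaluate = evaluate, electron_count = n_electrons, overlap = S)
}

#' Wrap a density function as a molecular density
#'
#' A `molecular_density` is the "total density" object consumed by the
#' partition: an evaluator over 3-space plus its electron count and the
#' site list it is associated with.
#'
#' @param evaluate function taking an n x 3 matrix of bohr positions and
#'   returning densities
#' @param electron_count total electrons the density integrates to
#' @param sites placed promolecule sites associated with the density
#' @return a `molecular_density` object
#' @export
molecular_density <- function(evaluate, electron_count, sites) {
  structure(list(evaluate = evaluate, electron_count = electron_count,
                 sites = sites),
            class = "molecular_density")
}

#' Promolecule as a molecular density
#'
#' @param sites placed sites from [place_sites()]
#' @return a `molecular_density` whose evaluator is the promolecule sum
#' @export
promolecule_as_molecular <- function(sites) {
  molecular_density(
    evaluate = function(points) promolecule_density(sites, points),
    electron_count = sum(vapply(sites, function(s) s$density$electron_count,
                                numeric(1))),
    sites = sites)
}
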