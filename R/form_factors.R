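#' Atomic form factors by numerical Fourier transform
#'
#' The aspherical form factor of a partitioned atomic density is its
#' Fourier transform about its own nucleus (atom-local phase convention):
#' f_A(h) = integral rho_A(r) exp(2 pi i h . (r - x_A)) d^3r.
#' The lattice phase exp(2 pi i h . x_A) is applied later, by the
#' structure-factor engine; .tsc tables are therefore per-atom and
#' position-free. Integration is an atom-centred spherical x radial
#' product quadrature (defaults: nominal-590 angular, 75-point
#' Mura-Knowles radial).
#'
#' @name form-factors
NULL

#' Spherical (radial) form factor
#'
#' f(s) = 4 pi integral rho(r) sinc(2 pi s r) r^2 dr with
#' sinc(x) = sin(x)/x, for a spherically symmetric density. f(0) equals
#' the electron count; for the single-zeta 1s family the closed form is
#' f(Q) = N_e * 16 zeta^4 / (4 zeta^2 + Q^2)^2 with Q = 2 pi s in atomic
#' units.
#'
#' @param rho a `radial_density`
#' @param s |reciprocal vector| in angstrom^-1 (vectorized), >= 0
#' @param rgrid radial quadrature grid (bohr)
#' @return real form factor values (electrons)
#' @export
spherical_form_factor <- function(rho, s, rgrid = radial_grid()) {
  if (any(s < 0)) stop("s must be non-negative")
  Q <- 2 * pi * s * BOHR_ANGSTROM   # per-bohr angular frequency
  r <- rgrid$radii
  dens <- rho$evaluate(r)
  vapply(Q, function(q) {
    sinc <- if (q == 0) rep(1, length(r)) else sin(q * r) / (q * r)
    4 * pi * sum(rgrid$weights * dens * sinc * r^2)
  }, numeric(1))
}

#' Closed-form 1s Slater form factor
#'
#' Analytic Fourier transform of the single-zeta 1s density, used as the
#' oracle for the numerical engine: f = N_e * 16 zeta^4/(4 zeta^2 + Q^2)^2,
#' Q = 2 pi s in bohr^-1.
#'
#' @param zeta screening exponent (bohr^-1)
#' @param s |reciprocal vector| (angstrom^-1), vectorized
#' @param electron_count electrons (default 1)
#' @return form factor (electrons)
#' @export
slater_form_factor <- function(zeta, s, electron_count = 1) {
  Q <- 2 * pi * s * BOHR_ANGSTROM
  electron_count * 16 * zeta^4 / (4 * zeta^2 + Q^2)^2
}

#' Aspherical form factor of a partitioned atomic density
#'
#' Numerical Fourier transform of rho_A = w_A * rho about the nucleus of
#' site A, on an atom-centred product grid.
#'
#' @param spec a [partition_spec()] (site positions in bohr)
#' @param total a [molecular_density()]
#' @param site_index which site
#' @param h_cart reciprocal vector(s), n x 3 matrix or length-3 vector,
#'   angstrom^-1
#' @param sgrid,rgrid quadrature grids
#' @return complex form factor(s) (electrons)
#' @export
aspherical_form_factor <- function(spec, total, site_index, h_cart,
                                   sgrid = sphere_grid(590),
                                   rgrid = radial_grid()) {
  h_cart <- .as_point_matrix(h_cart)
  if (any(!is.finite(h_cart))) stop("h must be finite")
  ctr <- spec$sites[[site_index]]$position
  pg <- product_grid(sgrid, rgrid)
  pts <- sweep(pg$offsets, 2, ctr, `+`)
  rho_a <- partitioned_atomic_density(spec, total, pts, site_index)
  v <- pg$weights * rho_a
  # phase 2 pi h . u with u in bohr, h in angstrom^-1
  P <- 2 * pi * BOHR_ANGSTROM * (pg$offsets %*% t(h_cart))
  drop(crossprod(v, exp(1i * P)))
}

#' Precompute a cached form-factor engine for a reflection list
#'
#' The atom-local grid offsets and the per-reflection phase factors
#' exp(2 pi i h . u) depend only on the quadrature grids and the hkl
#' list -- not on the site positions, the exponent n, or the ADPs. This
#' constructor computes the (expensive) cosine/sine phase matrices once;
#' the returned function then evaluates the whole form-factor table for
#' any geometry and exponent with two real matrix products per site.
#'
#' @param cell a [unit_cell()]
#' @param hkl n x 3 integer matrix of reflections
#' @param sgrid,rgrid quadrature grids
#' @param chunk reflections per phase-matrix chunk (memory control)
#' @return function `(spec, total)` returning the complex form-factor
#'   matrix (n_sites x n_hkl)
#' @export
form_factor_engine <- function(cell, hkl, sgrid = sphere_grid(590),
                               rgrid = radial_grid(), chunk = 1024L) {
  hkl <- .as_point_matrix(hkl)
  h_cart <- hkl_to_cart(cell, hkl)
  pg <- product_grid(sgrid, rgrid)
  n_h <- nrow(hkl)
  idx <- split(seq_len(n_h), ceiling(seq_len(n_h) / chunk))
  phases <- lapply(idx, function(j) {
    P <- 2 * pi * BOHR_ANGSTROM * (pg$offsets %*% t(h_cart[j, , drop = FALSE]))
    list(C = cos(P), S = sin(P))
  })
  force(pg)
  function(spec, total) {
    ns <- length(spec$sites)
    out <- matrix(complex(real = NA_real_), ns, n_h)
    for (a in seq_len(ns)) {
      ctr <- spec$sites[[a]]$position
      pts <- sweep(pg$offsets, 2, ctr, `+`)
      v <- pg$weights * partitioned_atomic_density(spec, total, pts, a)
      for (k in seq_along(idx)) {
        re <- drop(crossprod(v, phases[[k]]$C))
        im <- drop(crossprod(v, phases[[k]]$S))
        out[a, idx[[k]]] <- complex(real = re, imaginary = im)
      }
    }
    out
  }
}

#' Build a form-factor table for a structure
#'
#' Computes aspherical form factors for every (site, hkl) pair of a toy
#' structure under a given partition exponent. Positions are taken from
#' the structure (fractional, converted to bohr); the promolecule is the
#' structure's own site list with default (or supplied) radial densities.
#'
#' @param structure a [toy_structure()]
#' @param hkl n x 3 integer matrix; must be unique and non-empty
#' @param n partition exponent
#' @param total optional [molecular_density()]; default = the structure's
#'   promolecule
#' @param sgrid,rgrid quadrature grids
#' @param engine optional precomputed [form_factor_engine()] for this
#'   cell and hkl list (reused across geometries)
#' @return a `form_factor_table`: list with `site_labels`, `hkl`
#'   (matrix), `values` (complex n_sites x n_hkl matrix), `n`
#' @export
build_tsc <- function(structure, hkl, n = 1, total = NULL,
                      sgrid = sphere_grid(590), rgrid = radial_grid(),
                      engine = NULL) {
  hkl <- .as_point_matrix(hkl)
  if (nrow(hkl) == 0L) stop("hkl list must be non-empty")
  if (anyDuplicated(paste(hkl[, 1], hkl[, 2], hkl[, 3])))
    stop("duplicate hkl in reflection list")
  spec <- structure_partition_spec(structure, n)
  if (is.null(total)) total <- promolecule_as_molecular(spec$sites)
  if (is.null(engine))
    engine <- form_factor_engine(structure$cell, hkl, sgrid, rgrid)
  vals <- engine(spec, total)
  structure(list(site_labels = vapply(structure$sites, `[[`, character(1),
                                      "label"),
                 hkl = hkl, values = vals, n = n),
            class = "form_factor_table")
}

#' @export
print.form_factor_table <- function(x, ...) {
  cat(sprintf("<form_factor_table> %d sites x %d reflections (n = %g)\n",
              length(x$site_labels), nrow(x$hkl), x$n))
  invisible(x)
}

#' Write a form-factor table in .tsc format
#'
#' Minimal dialect: header lines `TITLE:`, `SYMM: expanded`,
#' `SCATTERERS:` (space-separated labels), then `DATA:` and one line per
#' reflection: `h k l` followed by one `re,im` pair per scatterer.
#'
#' @param table a `form_factor_table`
#' @param path output file
#' @param title title string for the header
#' @param digits significant digits for the values
#' @return `path`, invisibly
#' @export
write_tsc <- function(table, path, title = "exphar form factors",
                      digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("TITLE: ", title), "SYMM: expanded",
               paste0("SCATTERERS: ", paste(table$site_labels, collapse = " ")),
               "DATA:"), con)
  fmt <- function(z) paste0(signif(Re(z), digits), ",", signif(Im(z), digits))
  lines <- vapply(seq_len(nrow(table$hkl)), function(i) {
    paste(c(table$hkl[i, ], fmt(table$values[, i])), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a .tsc form-factor table
#'
#' Accepts the dialect written by [write_tsc()]; unknown header keys are
#' ignored.
#'
#' @param path .tsc file
#' @return a `form_factor_table`
#' @export
read_tsc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_at <- which(trimws(lines) == "DATA:")
  if (length(data_at) != 1L) stop("no DATA: section in ", path)
  header <- lines[seq_len(data_at - 1L)]
  sc_line <- grep("^SCATTERERS:", header, value = TRUE)
  if (length(sc_line) != 1L) stop("no SCATTERERS: header in ", path)
  labels <- strsplit(trimws(sub("^SCATTERERS:", "", sc_line)),
                     "[[:space:]]+")[[1]]
  body <- lines[(data_at + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  hkl <- t(vapply(parts, function(p) as.numeric(p[1:3]), numeric(3)))
  vals <- vapply(parts, function(p) {
    z <- vapply(strsplit(p[-(1:3)], ","), function(q) {
      complex(real = as.numeric(q[1]), imaginary = as.numeric(q[2]))
    }, complex(1))
    z
  }, complex(length(labels)))
  vals <- matrix(vals, nrow = length(labels))
  structure(list(site_labels = labels, hkl = hkl, values = vals, n = NA_real_),
            class = "form_factor_table")
}
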