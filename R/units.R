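# Unit conventions: electron densities and quadrature grids live in atomic
# units (bohr); crystallographic quantities (cells, positions, |h|) are in
# angstrom. Conversion happens once, at the crystallographic boundary.

#' Bohr radius in angstrom
#'
#' Conversion constant between the atomic-unit length scale used for
#' electron densities and the angstrom scale used for crystallography.
#' @export
BOHR_ANGSTROM <- 0.529177210903

#' Convert angstrom to bohr
#' @param x length(s) in angstrom
#' @return length(s) in bohr
#' @export
ang_to_bohr <- function(x) x / BOHR_ANGSTROM

#' Convert bohr to angstrom
#' @param x length(s) in bohr
#' @return length(s) in angstrom
#' @export
bohr_to_ang <- function(x) x * BOHR_ANGSTROM
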