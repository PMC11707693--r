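#' Toy crystal structures and crystallographic file I/O
#'
#' A toy structure is a P1 cell plus a list of sites, each carrying a
#' label, an element, a fractional position, a Cartesian ADP tensor and
#' an occupancy. Readers/writers cover a minimal CIF dialect (cell, P1
#' symmetry, atom_site and atom_site_aniso loops) and SHELX-style .hkl
#' reflection files.
#'
#' @name toy-structure
NULL

#' Construct a toy structure
#'
#' @param cell a [unit_cell()]
#' @param sites list of site lists with fields `label`, `element`,
#'   `frac` (length-3 fractional position), `U` (3x3 Cartesian ADP,
#'   angstrom^2), `occupancy` (in (0, 1\]); optional `zeta`,
#'   `electron_count` override the promolecule defaults
#' @return a `toy_structure`
#' @export
toy_structure <- function(cell, sites) {
  stopifnot(inherits(cell, "unit_cell"), length(sites) > 0)
  sites <- lapply(sites, function(s) {
    if (is.null(s$occupancy)) s$occupancy <- 1
    if (s$occupancy <= 0 || s$occupancy > 1) stop("occupancy must be in (0,1]")
    s$frac <- as.numeric(s$frac) %% 1
    s$U <- .as_U(adp_tensor(s$U))
    s
  })
  structure(list(cell = cell, sites = sites, space_group = "P 1"),
            class = "toy_structure")
}

#' @export
print.toy_structure <- function(x, ...) {
  print(x$cell)
  for (s in x$sites)
    cat(sprintf("  %-4s %-2s at (%.4f, %.4f, %.4f)  Ueq=%.5f  occ=%g\n",
                s$label, s$element, s$frac[1], s$frac[2], s$frac[3],
                u_eq(s$U), s$occupancy))
  invisible(x)
}

#' Promolecule partition spec for a structure
#'
#' Places the default (or per-site overridden) Slater densities at the
#' structure's Cartesian site positions, converted to bohr, and wraps
#' them in a [partition_spec()].
#'
#' @param structure a [toy_structure()]
#' @param n partition exponent
#' @return a [partition_spec()] in bohr coordinates
#' @export
structure_partition_spec <- function(structure, n = 1) {
  dens <- lapply(structure$sites, function(s) {
    slater_density(s$element, zeta = s$zeta,
                   electron_count = s$electron_count)
  })
  cart <- frac_to_cart(structure$cell,
                       t(vapply(structure$sites, `[[`, numeric(3), "frac")))
  partition_spec(place_sites(dens, ang_to_bohr(cart)), n = n)
}

#' Total electron density model for a structure
#'
#' Two density models over the structure's sites (positions in bohr,
#' promolecule weights always from the full isolated-atom densities):
#'
#' * `"promolecule"`: the plain superposition of isolated-atom densities.
#' * `"bonding"`: each bonded pair shares a two-electron LCAO bond
#'   orbital ([bond_pair_density()] built from the partners' own zeta
#'   exponents); every partner contributes one electron to each of its
#'   bonds and its atomic density is scaled down accordingly. The total
#'   electron count is unchanged, but density accumulates in the bond
#'   regions -- the situation in which the stockholder partition
#'   actually shares density between atoms.
#'
#' @param structure a [toy_structure()]
#' @param model `"promolecule"` or `"bonding"`
#' @param bonds list of index pairs (site_a, site_b) for the bonding
#'   model; default: every H site paired with the nearest non-H site
#' @return a [molecular_density()] (bohr coordinates)
#' @export
structure_total_density <- function(structure,
                                    model = c("promolecule", "bonding"),
                                    bonds = NULL) {
  model <- match.arg(model)
  spec <- structure_partition_spec(structure, 1)
  if (model == "promolecule") return(promolecule_as_molecular(spec$sites))
  elems <- vapply(structure$sites, `[[`, character(1), "element")
  pos <- t(vapply(spec$sites, `[[`, numeric(3), "position"))
  if (is.null(bonds)) {
    h_idx <- which(elems == "H"); x_idx <- which(elems != "H")
    if (!length(h_idx) || !length(x_idx))
      stop("bonding model needs at least one H and one non-H site")
    bonds <- lapply(h_idx, function(i) {
      d2 <- colSums((t(pos[x_idx, , drop = FALSE]) - pos[i, ])^2)
      c(x_idx[which.min(d2)], i)
    })
  }
  n_bonds_of <- tabulate(unlist(bonds), nbins = length(spec$sites))
  vz <- slater_valence_zeta_defaults()
  vzeta <- function(i) {
    el <- elems[i]
    if (el %in% names(vz)) vz[[el]] else spec$sites[[i]]$density$zeta
  }
  pair_terms <- lapply(bonds, function(bd) {
    bond_pair_density(pos[bd[1], ], pos[bd[2], ], vzeta(bd[1]), vzeta(bd[2]),
                      n_electrons = 2)
  })
  core_scale <- vapply(seq_along(spec$sites), function(i) {
    z <- spec$sites[[i]]$density$electron_count
    if (n_bonds_of[i] > z) stop("site ", i, " has more bonds than electrons")
    (z - n_bonds_of[i]) / z
  }, numeric(1))
  evaluate <- function(points) {
    points <- .as_point_matrix(points)
    m <- .site_density_matrix(spec$sites, points)
    core <- drop(m %*% core_scale)
    core + Reduce(`+`, lapply(pair_terms, function(p) p$evaluate(points)))
  }
  molecular_density(evaluate,
                    electron_count = sum(vapply(spec$sites, function(s)
                      s$density$electron_count, numeric(1))),
                    sites = spec$sites)
}

#' Enumerate Friedel-unique reflections to a resolution limit
#'
#' All P1 reflections with d >= d_min, one per Friedel pair (the
#' representative has h > 0, or h = 0 and k > 0, or h = k = 0 and l > 0),
#' excluding (0,0,0).
#'
#' @param cell a [unit_cell()]
#' @param d_min resolution limit (angstrom), > 0
#' @return integer matrix (n x 3), ordered by decreasing d
#' @export
generate_hkl <- function(cell, d_min) {
  if (d_min <= 0) stop("d_min must be > 0")
  smax <- 1 / d_min
  lim <- function(axis) ceiling(smax / sqrt(sum(cell$B[axis, ]^2)))
  h <- -lim(1):lim(1); k <- -lim(2):lim(2); l <- -lim(3):lim(3)
  hkl <- as.matrix(expand.grid(h = h, k = k, l = l))
  keep <- hkl[, 1] > 0 |
    (hkl[, 1] == 0 & hkl[, 2] > 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] > 0)
  hkl <- hkl[keep, , drop = FALSE]
  d <- d_spacing(cell, hkl)
  sel <- d >= d_min
  if (!any(sel)) stop("no reflections with d >= ", d_min, " angstrom")
  hkl <- hkl[sel, , drop = FALSE]
  hkl[order(-d[sel]), , drop = FALSE]
}

#' Write a minimal P1 CIF
#'
#' Cell, P1 symmetry, atom_site loop (with U_eq) and atom_site_aniso
#' loop; anisotropic U is written in the CIF reciprocal-basis convention
#' via [u_cart_to_cif()].
#'
#' @param structure a [toy_structure()]
#' @param path output file
#' @param data_name CIF data block name
#' @return `path`, invisibly
#' @export
write_cif <- function(structure, path, data_name = "toy") {
  cl <- structure$cell
  out <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a %.6f", cl$a),
    sprintf("_cell_length_b %.6f", cl$b),
    sprintf("_cell_length_c %.6f", cl$c),
    sprintf("_cell_angle_alpha %.6f", cl$alpha),
    sprintf("_cell_angle_beta %.6f", cl$beta),
    sprintf("_cell_angle_gamma %.6f", cl$gamma),
    "_space_group_name_H-M_alt 'P 1'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_U_iso_or_equiv")
  for (s in structure$sites)
    out <- c(out, sprintf("%s %s %.8f %.8f %.8f %.6f %.8f",
                          s$label, s$element, s$frac[1], s$frac[2], s$frac[3],
                          s$occupancy, u_eq(s$U)))
  out <- c(out,
    "loop_",
    "_atom_site_aniso_label",
    "_atom_site_aniso_U_11",
    "_atom_site_aniso_U_22",
    "_atom_site_aniso_U_33",
    "_atom_site_aniso_U_12",
    "_atom_site_aniso_U_13",
    "_atom_site_aniso_U_23")
  for (s in structure$sites) {
    uc <- u_cart_to_cif(cl, s$U)
    out <- c(out, sprintf("%s %.8f %.8f %.8f %.8f %.8f %.8f",
                          s$label, uc[1, 1], uc[2, 2], uc[3, 3],
                          uc[1, 2], uc[1, 3], uc[2, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a minimal P1 CIF
#'
#' Parses the dialect written by [write_cif()] (cell, atom_site loop,
#' optional atom_site_aniso loop). Anisotropic U values are converted
#' from the CIF reciprocal-basis convention to Cartesian; atoms without
#' aniso entries get an isotropic U from U_iso_or_equiv.
#'
#' @param path CIF file
#' @return a [toy_structure()]
#' @export
read_cif <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  val <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)[1]
    as.numeric(strsplit(ln, "[[:space:]]+")[[1]][2])
  }
  cell <- unit_cell(val("_cell_length_a"), val("_cell_length_b"),
                    val("_cell_length_c"), val("_cell_angle_alpha"),
                    val("_cell_angle_beta"), val("_cell_angle_gamma"))
  read_loop <- function(first_tag) {
    start <- grep(paste0("^", first_tag, "$"), lines)
    if (length(start) == 0L) return(NULL)
    i <- start[1]
    # collect tag lines upward to loop_, then data rows
    tags <- character()
    j <- i
    while (j <= length(lines) && grepl("^_", lines[j])) {
      tags <- c(tags, lines[j]); j <- j + 1
    }
    rows <- list()
    while (j <= length(lines) && nzchar(lines[j]) &&
           !grepl("^(_|loop_|data_)", lines[j])) {
      rows[[length(rows) + 1L]] <- strsplit(lines[j], "[[:space:]]+")[[1]]
      j <- j + 1
    }
    list(tags = tags, rows = rows)
  }
  main <- read_loop("_atom_site_label")
  if (is.null(main)) stop("no atom_site loop in ", path)
  col <- function(loop, tag) match(tag, loop$tags)
  aniso <- read_loop("_atom_site_aniso_label")
  aniso_map <- list()
  if (!is.null(aniso)) {
    for (r in aniso$rows) {
      u <- as.numeric(r[c(col(aniso, "_atom_site_aniso_U_11"),
                          col(aniso, "_atom_site_aniso_U_22"),
                          col(aniso, "_atom_site_aniso_U_33"),
                          col(aniso, "_atom_site_aniso_U_12"),
                          col(aniso, "_atom_site_aniso_U_13"),
                          col(aniso, "_atom_site_aniso_U_23"))])
      aniso_map[[r[col(aniso, "_atom_site_aniso_label")]]] <-
        u_cif_to_cart(cell, u)
    }
  }
  sites <- lapply(main$rows, function(r) {
    label <- r[col(main, "_atom_site_label")]
    U <- aniso_map[[label]]
    if (is.null(U)) {
      ueq <- as.numeric(r[col(main, "_atom_site_U_iso_or_equiv")])
      U <- diag(ueq, 3)
    }
    occ_col <- col(main, "_atom_site_occupancy")
    list(label = label,
         element = r[col(main, "_atom_site_type_symbol")],
         frac = as.numeric(r[c(col(main, "_atom_site_fract_x"),
                               col(main, "_atom_site_fract_y"),
                               col(main, "_atom_site_fract_z"))]),
         U = U,
         occupancy = if (is.na(occ_col)) 1 else as.numeric(r[occ_col]))
  })
  toy_structure(cell, sites)
}

#' Construct reflection data
#'
#' @param hkl n x 3 integer matrix
#' @param f_obs_sq observed intensities F_o^2 (arbitrary scale)
#' @param sigma positive uncertainties of F_o^2
#' @param cell a [unit_cell()] for d-spacings
#' @return a `reflection_data` tibble with columns `h`, `k`, `l`,
#'   `f_obs_sq`, `sigma`, `d`
#' @export
reflection_data <- function(hkl, f_obs_sq, sigma, cell) {
  hkl <- .as_point_matrix(hkl)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (anyDuplicated(paste(hkl[, 1], hkl[, 2], hkl[, 3])))
    stop("duplicate hkl")
  out <- tibble::tibble(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                        l = as.integer(hkl[, 3]),
                        f_obs_sq = as.numeric(f_obs_sq),
                        sigma = as.numeric(sigma),
                        d = d_spacing(cell, hkl))
  class(out) <- c("reflection_data", class(out))
  out
}

#' Write SHELX-style .hkl reflection data
#'
#' Whitespace-separated `h k l Fo^2 sigma` lines with a terminating
#' `0 0 0 0 0` record.
#'
#' @param data a [reflection_data()] tibble
#' @param path output file
#' @return `path`, invisibly
#' @export
write_hkl <- function(data, path) {
  lines <- sprintf("%4d %4d %4d %14.6f %14.6f",
                   data$h, data$k, data$l, data$f_obs_sq, data$sigma)
  writeLines(c(lines, sprintf("%4d %4d %4d %14.6f %14.6f", 0, 0, 0, 0, 0)),
             path)
  invisible(path)
}

#' Read SHELX-style .hkl reflection data
#'
#' Accepts whitespace-separated or fixed-width (3,3,3 then free) columns
#' `h k l Fo^2 sigma`; the `0 0 0` terminator line and anything after it
#' are ignored.
#'
#' @param path .hkl file
#' @param cell a [unit_cell()] for d-spacings
#' @return a [reflection_data()] tibble
#' @export
read_hkl <- function(path, cell) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse1 <- function(ln) {
    p <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(p) >= 5 && !anyNA(suppressWarnings(as.numeric(p[1:5]))))
      return(as.numeric(p[1:5]))
    # fixed-width fallback: 3+3+3 integer columns then two floats
    h <- suppressWarnings(as.numeric(substr(ln, 1, 4)))
    k <- suppressWarnings(as.numeric(substr(ln, 5, 8)))
    l <- suppressWarnings(as.numeric(substr(ln, 9, 12)))
    rest <- strsplit(trimws(substr(ln, 13, nchar(ln))), "[[:space:]]+")[[1]]
    c(h, k, l, as.numeric(rest[1]), as.numeric(rest[2]))
  }
  m <- t(vapply(lines, parse1, numeric(5), USE.NAMES = FALSE))
  term <- which(m[, 1] == 0 & m[, 2] == 0 & m[, 3] == 0)
  if (length(term)) m <- m[seq_len(term[1] - 1L), , drop = FALSE]
  reflection_data(m[, 1:3, drop = FALSE], m[, 4], m[, 5], cell)
}
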