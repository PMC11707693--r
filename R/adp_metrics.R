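#' Anisotropic displacement parameter (ADP) similarity statistics
#'
#' An ADP is a 3x3 symmetric tensor U (angstrom^2, Cartesian convention
#' throughout this module) describing the Gaussian smearing of an atom by
#' thermal and static displacement. The module provides:
#'
#' * directional mean-square displacement MSD_n(U) = n' U n and its root,
#' * the equivalent isotropic displacement U_eq = tr(U)/3 (also the
#'   spherical average of MSD),
#' * MSD_corr: a Pearson-style correlation of two atoms' directional MSD
#'   fields over uniformly distributed directions -- independent of the
#'   overall scale and of isotropic shifts of either tensor, undefined
#'   for isotropic ADPs,
#' * the Gaussian overlapping coefficient OVL of the two zero-mean
#'   trivariate displacement distributions, with eta = 1 - OVL and its
#'   percent form eta_r,
#' * Merritt's correlation coefficient CC and the S12 index
#'   S12 = 100 (1 - CC),
#' * the single-parameter isotropic ADP scale q mapping one set of
#'   tensors onto a reference set,
#' * bond-length discrepancy statistics <|dd|> and <dd>.
#'
#' @name adp-metrics
NULL

#' Construct an ADP tensor
#'
#' @param U 3x3 symmetric matrix (angstrom^2, Cartesian) or length-6
#'   vector (U11, U22, U33, U12, U13, U23)
#' @param label atom label
#' @return an `adp_tensor` object (the symmetrized matrix with attributes)
#' @export
adp_tensor <- function(U, label = "") {
  if (length(U) == 6L)
    U <- matrix(c(U[1], U[4], U[5], U[4], U[2], U[6], U[5], U[6], U[3]), 3, 3)
  U <- as.matrix(U)
  if (!all(dim(U) == c(3, 3))) stop("U must be 3x3")
  if (max(abs(U - t(U))) > 1e-12 * max(1, max(abs(U))))
    stop("U must be symmetric")
  U <- (U + t(U)) / 2
  structure(U, label = label, class = c("adp_tensor", "matrix", "array"))
}

.as_U <- function(U) {
  if (inherits(U, "adp_tensor")) return(unclass(U)[1:3, 1:3])
  adp_tensor(U)[1:3, 1:3]
}

#' Is an ADP tensor isotropic?
#'
#' Flags tensors whose eigenvalue spread relative to U_eq is below `tol`.
#' MSD_corr is undefined for such tensors.
#'
#' @param U ADP tensor
#' @param tol relative eigenvalue-spread tolerance (default 1e-9)
#' @return logical
#' @export
adp_is_isotropic <- function(U, tol = 1e-9) {
  U <- .as_U(U)
  ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  (max(ev) - min(ev)) <= tol * max(abs(ev), .Machine$double.xmin)
}

#' Directional mean-square displacement
#'
#' MSD_n(U) = n' U n, the mean square of the displacement projected on
#' the unit direction n. `rmsd` returns its square root (used for peanut
#' plots).
#'
#' @param U ADP tensor (angstrom^2)
#' @param direction direction vector; must be unit length to 1e-9 in
#'   strict mode, otherwise it is normalized with a warning
#' @param strict error on non-unit directions instead of normalizing
#' @return MSD in angstrom^2 (or RMSD in angstrom)
#' @export
msd <- function(U, direction, strict = FALSE) {
  U <- .as_U(U)
  nv <- as.numeric(direction)
  len <- sqrt(sum(nv^2))
  if (abs(len - 1) > 1e-9) {
    if (strict) stop("direction must be a unit vector")
    warning("normalizing non-unit direction")
    nv <- nv / len
  }
  drop(nv %*% U %*% nv)
}

#' @rdname msd
#' @export
rmsd <- function(U, direction, strict = FALSE) sqrt(msd(U, direction, strict))

#' Equivalent isotropic displacement parameter
#'
#' U_eq = tr(U)/3, equal to the average of MSD_n over uniformly
#' distributed directions.
#'
#' @param U ADP tensor
#' @return U_eq (angstrom^2)
#' @export
u_eq <- function(U) {
  U <- .as_U(U)
  sum(diag(U)) / 3
}

# second moment <MSD> and the covariance of two MSD fields over uniform
# directions; isotropic fourth-moment identity
# <n_i n_j n_k n_l> = (d_ij d_kl + d_ik d_jl + d_il d_jk)/15 gives
# <MSD(U1) MSD(U2)> = [tr U1 tr U2 + 2 tr(U1 U2)]/15, hence
# cov = (2/15) [tr(U1 U2) - tr U1 tr U2 / 3].
.msd_cov <- function(U1, U2) {
  (2 / 15) * (sum(U1 * U2) - sum(diag(U1)) * sum(diag(U2)) / 3)
}

#' MSD correlation of two ADP tensors
#'
#' Pearson-style correlation of the directional MSD fields of two ADPs
#' over uniformly distributed directions. Independent of the scale of
#' either tensor and unchanged by adding c*I to either; it ranges over
#' \[-1, 1\] and is undefined for isotropic ADPs (returns `NA` with a
#' warning).
#'
#' Two evaluation paths are provided and agree to ~1e-6 and better:
#' * `"analytic"`: closed form from the isotropic fourth-moment identity,
#'   cor = \[tr(U1 U2) - tr U1 tr U2 / 3\] / (sd1 * sd2) with
#'   sd_i^2 = tr(U_i^2) - (tr U_i)^2/3.
#' * `"quadrature"`: direction-space numerical integration on the
#'   degree-131 spherical grid (the nominal 5810-point order).
#'
#' @param U1,U2 ADP tensors (angstrom^2, Cartesian)
#' @param method `"analytic"` (default) or `"quadrature"`
#' @param iso_tol isotropy tolerance passed to [adp_is_isotropic()]
#' @return correlation in \[-1, 1\], or `NA_real_` if either input is
#'   isotropic
#' @examples
#' msd_corr(diag(c(2, 1, 1)), diag(c(1, 2, 2)))  # -1
#' @export
msd_corr <- function(U1, U2, method = c("analytic", "quadrature"),
                     iso_tol = 1e-9) {
  method <- match.arg(method)
  U1 <- .as_U(U1); U2 <- .as_U(U2)
  if (adp_is_isotropic(U1, iso_tol) || adp_is_isotropic(U2, iso_tol)) {
    warning("MSD_corr is undefined for isotropic ADPs; returning NA")
    return(NA_real_)
  }
  if (method == "analytic") {
    num <- .msd_cov(U1, U2)
    den <- sqrt(.msd_cov(U1, U1) * .msd_cov(U2, U2))
    val <- num / den
  } else {
    g <- sphere_grid(5810)
    m1 <- rowSums((g$points %*% U1) * g$points)
    m2 <- rowSums((g$points %*% U2) * g$points)
    mu1 <- sum(g$weights * m1); mu2 <- sum(g$weights * m2)
    num <- sum(g$weights * (m1 - mu1) * (m2 - mu2))
    den <- sqrt(sum(g$weights * (m1 - mu1)^2) *
                sum(g$weights * (m2 - mu2)^2))
    val <- num / den
  }
  max(-1, min(1, val))
}

# P(sum a_i z_i^2 <= t) for z ~ N(0, I), by Imhof characteristic-function
# inversion. Deterministic; used for the overlapping coefficient.
.imhof_cdf <- function(a, t) {
  a <- a[abs(a) > 0]
  if (length(a) == 0L) return(as.numeric(t >= 0))
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(a, u))) - 0.5 * t * u
    rho <- exp(0.25 * colSums(log1p(outer(a^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                          abs.tol = 1e-12, subdivisions = 2000L,
                          stop.on.error = FALSE)$value
  min(1, max(0, 0.5 - val / pi))
}

#' Gaussian overlapping coefficient of two ADPs
#'
#' Treats each ADP as the covariance of a zero-mean trivariate normal
#' displacement distribution p_i(u) and computes the overlapping
#' coefficient OVL = integral min(p1, p2) d^3u, together with
#' eta = (1/2) integral |p1 - p2| d^3u = 1 - OVL and its percent form
#' eta_r = 100 * eta (the percentage of probability mass by which the
#' two displacement PDFs differ).
#'
#' Evaluation is exact up to 1D numerical inversion: in the frame
#' diagonalizing U1^(-1/2) U2 U1^(-1/2) the acceptance regions are level
#' sets of a quadratic form in normal variables, whose probabilities are
#' computed by Imhof characteristic-function inversion. Unlike MSD_corr,
#' the index is scale-dependent.
#'
#' @param U1,U2 positive-definite ADP tensors (angstrom^2)
#' @return list with `ovl`, `eta`, `eta_r`
#' @export
gaussian_overlap <- function(U1, U2) {
  U1 <- .as_U(U1); U2 <- .as_U(U2)
  e1 <- eigen(U1, symmetric = TRUE)
  e2v <- eigen(U2, symmetric = TRUE, only.values = TRUE)$values
  if (min(e1$values) <= 0 || min(e2v) <= 0)
    stop("ADP tensors must be positive definite")
  # whiten by U1: M = U1^-1/2 U2 U1^-1/2, eigenvalues lambda
  W <- e1$vectors %*% diag(1 / sqrt(e1$values)) %*% t(e1$vectors)
  M <- W %*% U2 %*% W
  lambda <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(lambda - 1)) < 1e-12)
    return(list(ovl = 1, eta = 0, eta_r = 0))
  # p1 > p2  <=>  sum (1/lambda_i - 1) u_i^2 > -sum log lambda_i  (u ~ frame
  # coords). OVL = P1(p1 <= p2) + P2(p1 > p2).
  t0 <- -sum(log(lambda))
  a1 <- 1 / lambda - 1          # u ~ N(0, I) under p1
  a2 <- (1 - lambda)            # u_i = sqrt(lambda_i) z_i under p2
  p1_le <- .imhof_cdf(a1, t0)   # P1(Q <= t0) i.e. p1 <= p2 region
  p2_gt <- 1 - .imhof_cdf(a2, t0)
  ovl <- min(1, max(0, p1_le + p2_gt))
  eta <- 1 - ovl
  list(ovl = ovl, eta = eta, eta_r = 100 * eta)
}

#' Merritt correlation coefficient and S12 index
#'
#' CC = integral p1 p2 / sqrt(integral p1^2 * integral p2^2) for the two
#' zero-mean Gaussians with covariances U1, U2, in closed form:
#' CC = 2^(3/2) (det U1 det U2)^(1/4) / det(U1 + U2)^(1/2).
#' S12 = 100 (1 - CC) by definition. CC is sensitive to a relative
#' scaling of the two tensors (CC(U, kU) < 1 for k != 1).
#'
#' @param U1,U2 positive-definite ADP tensors
#' @return list with `cc` and `s12`
#' @export
merritt_cc <- function(U1, U2) {
  U1 <- .as_U(U1); U2 <- .as_U(U2)
  d1 <- det(U1); d2 <- det(U2)
  if (d1 <= 0 || d2 <= 0 ||
      min(eigen(U1, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(U2, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("ADP tensors must be positive definite")
  cc <- 2^(3 / 2) * (d1 * d2)^(1 / 4) / sqrt(det(U1 + U2))
  list(cc = cc, s12 = 100 * (1 - cc))
}

#' Isotropic ADP scale factor q
#'
#' The single multiplicative factor best mapping a set of target ADPs
#' onto an aligned reference set. Two estimators:
#' * `"frobenius"` (default): q = argmin sum ||U_ref - q U_tgt||_F^2
#'   = sum tr(U_ref U_tgt) / sum tr(U_tgt^2);
#' * `"ueq"`: q = mean(U_eq,ref) / mean(U_eq,tgt).
#'
#' @param reference,target equal-length lists of ADP tensors (aligned by
#'   atom)
#' @param method `"frobenius"` or `"ueq"`
#' @return the scale q
#' @export
fit_isotropic_scale <- function(reference, target,
                                method = c("frobenius", "ueq")) {
  method <- match.arg(method)
  if (length(reference) == 0L || length(reference) != length(target))
    stop("reference and target must be non-empty aligned lists")
  Ur <- lapply(reference, .as_U); Ut <- lapply(target, .as_U)
  if (method == "frobenius") {
    num <- sum(mapply(function(a, b) sum(a * b), Ur, Ut))
    den <- sum(vapply(Ut, function(b) sum(b * b), numeric(1)))
    num / den
  } else {
    mean(vapply(Ur, u_eq, numeric(1))) / mean(vapply(Ut, u_eq, numeric(1)))
  }
}

#' Bond-length discrepancy statistics
#'
#' Mean absolute and signed differences between aligned bond-length
#' lists, <|dd|> = mean |d_x - d_ref| and <dd> = mean (d_x - d_ref).
#'
#' @param bonds_x,bonds_ref aligned numeric vectors of bond lengths
#'   (angstrom)
#' @param unit `"angstrom"` or `"mAngstrom"` (milli-angstrom) for the
#'   returned values
#' @return list with `mean_abs_delta` and `mean_delta`
#' @export
bond_length_stats <- function(bonds_x, bonds_ref,
                              unit = c("angstrom", "mAngstrom")) {
  unit <- match.arg(unit)
  if (length(bonds_x) == 0L || length(bonds_x) != length(bonds_ref))
    stop("bond lists must be non-empty and aligned")
  d <- bonds_x - bonds_ref
  s <- if (unit == "mAngstrom") 1000 else 1
  list(mean_abs_delta = s * mean(abs(d)), mean_delta = s * mean(d))
}

#' Compare two aligned sets of ADPs
#'
#' Per-atom ADP similarity report: MSD_corr, overlapping coefficient
#' (ovl, eta_r), Merritt CC / S12 and the U_eq ratio, one row per atom,
#' plus summary means as attributes. Atoms whose MSD_corr is undefined
#' (isotropic) contribute `NA` and are skipped in the summary mean, with
#' the skipped count reported.
#'
#' @param reference,target aligned lists of ADP tensors
#' @param labels optional atom labels (default from tensor labels or
#'   index)
#' @return a tibble (class `adp_comparison`) with columns `atom`,
#'   `msd_corr`, `ovl`, `eta_r`, `cc`, `s12`, `ueq_ratio`; attributes
#'   `summary` (named means) and `n_isotropic_skipped`
#' @export
compare_adps <- function(reference, target, labels = NULL) {
  if (length(reference) == 0L || length(reference) != length(target))
    stop("reference and target must be non-empty aligned lists")
  if (is.null(labels)) {
    labels <- vapply(seq_along(reference), function(i) {
      l <- attr(reference[[i]], "label")
      if (is.null(l) || !nzchar(l)) paste0("atom", i) else l
    }, character(1))
  }
  rows <- lapply(seq_along(reference), function(i) {
    u1 <- .as_U(reference[[i]]); u2 <- .as_U(target[[i]])
    mc <- suppressWarnings(msd_corr(u1, u2))
    go <- gaussian_overlap(u1, u2)
    mcc <- merritt_cc(u1, u2)
    tibble::tibble(atom = labels[i], msd_corr = mc, ovl = go$ovl,
                   eta_r = go$eta_r, cc = mcc$cc, s12 = mcc$s12,
                   ueq_ratio = u_eq(u2) / u_eq(u1))
  })
  out <- dplyr::bind_rows(rows)
  summ <- c(msd_corr = mean(out$msd_corr, na.rm = TRUE),
            ovl = mean(out$ovl), eta_r = mean(out$eta_r),
            cc = mean(out$cc), s12 = mean(out$s12),
            ueq_ratio = mean(out$ueq_ratio),
            q_frobenius = fit_isotropic_scale(reference, target))
  attr(out, "summary") <- summ
  attr(out, "n_isotropic_skipped") <- sum(is.na(out$msd_corr))
  class(out) <- c("adp_comparison", class(out))
  out
}
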