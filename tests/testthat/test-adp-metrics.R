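test_that("directional MSD is the quadratic form n'Un", {
  U <- diag(c(2, 1, 1))
  expect_equal(msd(U, c(1, 0, 0)), 2)
  expect_equal(msd(U, c(0, 1, 0)), 1)
  set.seed(5)
  for (i in 1:5) {
    Ur <- random_spd()
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    brute <- sum(outer(v, v) * Ur)
    expect_equal(msd(Ur, v), brute, tolerance = 1e-12)
    expect_equal(rmsd(Ur, v), sqrt(brute), tolerance = 1e-12)
  }
  expect_warning(msd(U, c(2, 0, 0)), "normalizing")
  expect_error(msd(U, c(2, 0, 0), strict = TRUE), "unit vector")
})

test_that("U_eq equals trace/3 and the spherical average of MSD", {
  expect_equal(u_eq(diag(c(2, 1, 1))), 4 / 3)
  expect_equal(u_eq(diag(3)), 1)
  set.seed(9)
  U <- random_spd()
  g <- sphere_grid(5810)
  quad_avg <- sum(g$weights * rowSums((g$points %*% U) * g$points))
  expect_equal(u_eq(U), quad_avg, tolerance = 1e-10)
})

test_that("MSD_corr reproduces the five printed worked examples", {
  cases <- list(
    list(diag(c(2, 1, 1)), diag(c(1, 2, 2)), -1),
    list(diag(c(2, 1, 1)), diag(c(1, 2, 1)), -0.5),
    list(diag(c(2, 1, 1)), diag(c(2, 2, 1)),  0.5),
    list(diag(c(2, 1, 1)), diag(c(3, 1, 1)),  1),
    list(diag(c(3, 3, 2)), diag(c(3, 1, 2)),  0))
  for (cs in cases) {
    expect_equal(msd_corr(cs[[1]], cs[[2]]), cs[[3]], tolerance = 1e-6)
    expect_equal(msd_corr(cs[[1]], cs[[2]], method = "quadrature"),
                 cs[[3]], tolerance = 1e-3)
  }
})

test_that("MSD_corr is symmetric, rotation invariant, shift invariant and bounded", {
  set.seed(21)
  for (i in 1:100) {
    U1 <- random_spd(); U2 <- random_spd()
    v <- msd_corr(U1, U2)
    expect_true(v >= -1 && v <= 1)
    expect_equal(v, msd_corr(U2, U1), tolerance = 1e-12)
    # common rotation
    qrres <- qr(matrix(stats::rnorm(9), 3)); R <- qr.Q(qrres)
    expect_equal(msd_corr(R %*% U1 %*% t(R), R %*% U2 %*% t(R)), v,
                 tolerance = 1e-10)
    # adding c*I to either argument changes nothing
    cshift <- stats::runif(1, 0, 0.05)
    expect_equal(msd_corr(U1 + cshift * diag(3), U2), v, tolerance = 1e-9)
    expect_equal(msd_corr(U1, U2 + cshift * diag(3)), v, tolerance = 1e-9)
  }
})

test_that("analytic and 5810-point quadrature MSD_corr agree on random pairs", {
  set.seed(33)
  for (i in 1:100) {
    U1 <- random_spd(); U2 <- random_spd()
    expect_equal(msd_corr(U1, U2),
                 msd_corr(U1, U2, method = "quadrature"),
                 tolerance = 1e-6)
  }
})

test_that("MSD_corr is undefined (NA with warning) for isotropic input", {
  expect_warning(v <- msd_corr(diag(3) * 0.02, diag(c(2, 1, 1))),
                 "undefined")
  expect_true(is.na(v))
  expect_true(adp_is_isotropic(diag(3) * 0.05))
  expect_false(adp_is_isotropic(diag(c(2, 1, 1))))
})

test_that("Gaussian overlap matches a dense 1D radial oracle for isotropic pairs", {
  s1 <- 0.02; s2 <- 0.035
  go <- gaussian_overlap(diag(s1, 3), diag(s2, 3))
  p <- function(r, s) exp(-r^2 / (2 * s)) / (2 * pi * s)^1.5
  eta_1d <- 0.5 * stats::integrate(
    function(r) abs(p(r, s1) - p(r, s2)) * 4 * pi * r^2,
    0, Inf, rel.tol = 1e-12)$value
  expect_equal(go$eta, eta_1d, tolerance = 1e-6)
  expect_equal(go$ovl + go$eta, 1, tolerance = 1e-10)
  expect_equal(go$eta_r, 100 * go$eta)
  # identical tensors
  same <- gaussian_overlap(diag(s1, 3), diag(s1, 3))
  expect_equal(same$ovl, 1)
  expect_equal(same$eta_r, 0)
  expect_error(gaussian_overlap(diag(c(1, 1, -1)), diag(3)),
               "positive definite")
})

test_that("Gaussian overlap agrees with a seeded Monte Carlo oracle on an anisotropic pair", {
  set.seed(77)
  U1 <- random_spd(); U2 <- random_spd()
  go <- gaussian_overlap(U1, U2)
  # mixture importance sampling of integral min(p1, p2)
  nmc <- 1e6
  L1 <- chol(U1); L2 <- chol(U2)
  z <- matrix(stats::rnorm(3 * nmc), ncol = 3)
  x <- rbind(z[seq_len(nmc / 2), ] %*% L1, z[-seq_len(nmc / 2), ] %*% L2)
  dens <- function(x, U) {
    iU <- solve(U)
    q <- rowSums((x %*% iU) * x)
    exp(-q / 2) / sqrt((2 * pi)^3 * det(U))
  }
  p1 <- dens(x, U1); p2 <- dens(x, U2)
  ratio <- pmin(p1, p2) / (0.5 * (p1 + p2))
  est <- mean(ratio); se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(go$ovl - est), 3 * se)
})

test_that("overlap is invariant under common rotations and common scalings", {
  set.seed(13)
  U1 <- random_spd(); U2 <- random_spd()
  base <- gaussian_overlap(U1, U2)$ovl
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  expect_equal(gaussian_overlap(R %*% U1 %*% t(R), R %*% U2 %*% t(R))$ovl,
               base, tolerance = 1e-7)
  expect_equal(gaussian_overlap(2.5 * U1, 2.5 * U2)$ovl, base,
               tolerance = 1e-7)
})

test_that("Merritt CC matches brute-force Gaussian-product quadrature and defines S12", {
  # brute-force Gaussian-product integral by tensor Gauss-Hermite
  # quadrature: integral p1 p2 = E_{x ~ p1}[p2(x)]
  gh <- pracma::gaussHermite(40)
  u3 <- as.matrix(expand.grid(gh$x, gh$x, gh$x))
  w3 <- apply(as.matrix(expand.grid(gh$w, gh$w, gh$w)), 1, prod)
  gauss_int <- function(Ua, Ub) {
    A <- t(chol(Ua))
    x <- sqrt(2) * u3 %*% t(A)
    iB <- solve(Ub)
    q <- rowSums((x %*% iB) * x)
    p2 <- exp(-q / 2) / sqrt((2 * pi)^3 * det(Ub))
    pi^(-3 / 2) * sum(w3 * p2)
  }
  set.seed(55)
  for (i in 1:20) {
    U1 <- random_spd(); U2 <- random_spd()
    res <- merritt_cc(U1, U2)
    cc_brute <- gauss_int(U1, U2) / sqrt(gauss_int(U1, U1) * gauss_int(U2, U2))
    expect_equal(res$cc, cc_brute, tolerance = 1e-8)
    expect_identical(res$s12, 100 * (1 - res$cc))
    expect_true(res$cc <= 1 + 1e-12)
  }
  same <- merritt_cc(diag(0.02, 3), diag(0.02, 3))
  expect_equal(same$cc, 1)
  expect_equal(same$s12, 0)
  # scale sensitivity: cc(U, kU) < 1 for k != 1
  U <- random_spd()
  expect_lt(merritt_cc(U, 1.7 * U)$cc, 1)
})

test_that("isotropic scale fit recovers exact scalings and matches a grid-search oracle", {
  set.seed(19)
  ref <- lapply(1:6, function(i) random_spd())
  expect_equal(fit_isotropic_scale(ref, ref), 1)
  expect_equal(fit_isotropic_scale(ref, lapply(ref, function(u) u / 0.9)),
               0.9, tolerance = 1e-12)
  tgt <- lapply(ref, function(u) u * 1.1 + 0.002 * crossprod(matrix(stats::rnorm(9), 3)))
  q_fit <- fit_isotropic_scale(ref, tgt)
  qs <- seq(0.5, 1.5, by = 1e-5)
  loss <- vapply(qs, function(q)
    sum(vapply(seq_along(ref), function(i)
      sum((ref[[i]] - q * tgt[[i]])^2), numeric(1))), numeric(1))
  expect_equal(q_fit, qs[which.min(loss)], tolerance = 1e-4)
  # ueq variant
  expect_equal(fit_isotropic_scale(ref, lapply(ref, function(u) u / 0.8),
                                   method = "ueq"), 0.8, tolerance = 1e-12)
  expect_error(fit_isotropic_scale(list(), list()), "non-empty")
})

test_that("bond-length statistics match direct arithmetic", {
  expect_equal(bond_length_stats(c(1, 1.1), c(1, 1.1)),
               list(mean_abs_delta = 0, mean_delta = 0))
  st <- bond_length_stats(c(1.01, 0.99), c(1.00, 1.00), unit = "mAngstrom")
  expect_equal(st$mean_abs_delta, 10)
  expect_equal(st$mean_delta, 0)
  set.seed(2)
  a <- stats::runif(7, 0.9, 1.1); b <- stats::runif(7, 0.9, 1.1)
  st2 <- bond_length_stats(a, b)
  expect_equal(st2$mean_abs_delta, mean(abs(a - b)))
  expect_equal(st2$mean_delta, mean(a - b))
  expect_error(bond_length_stats(1, c(1, 2)), "aligned")
})

test_that("compare_adps reports per-atom metrics, summary means and skipped isotropics", {
  set.seed(4)
  ref <- list(random_spd(), random_spd(), diag(0.02, 3))
  tgt <- list(random_spd(), random_spd(), diag(0.025, 3))
  cmp <- suppressWarnings(compare_adps(ref, tgt, labels = c("H1", "H2", "C1")))
  expect_s3_class(cmp, "adp_comparison")
  expect_equal(nrow(cmp), 3)
  expect_equal(attr(cmp, "n_isotropic_skipped"), 1)
  expect_equal(cmp$s12, 100 * (1 - cmp$cc))
  expect_equal(cmp$ovl + (cmp$eta_r / 100), rep(1, 3), tolerance = 1e-9)
  g <- glance(cmp)
  expect_equal(g$msd_corr, mean(cmp$msd_corr, na.rm = TRUE))
  expect_true("q_frobenius" %in% names(g))
})
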