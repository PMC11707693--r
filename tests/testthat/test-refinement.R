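# small shared setup: diatomic toy, d_min = 1.0 for speed in unit tests
local_toy <- local({
  st <- make_structure("diatomic_XH", 1)
  hkl <- generate_hkl(st$cell, 1.0)
  engine <- form_factor_engine(st$cell, hkl)
  provider <- function(s2) build_tsc(
    s2, hkl, n = 1, engine = engine,
    total = structure_total_density(s2, "promolecule"))
  list(st = st, hkl = hkl, engine = engine, provider = provider)
})

test_that("structure factors match a two-term oracle and obey Friedel symmetry", {
  cell <- unit_cell(6, 6, 6)
  x <- 0.13
  st2 <- toy_structure(cell, list(
    list(label = "H1", element = "H", frac = c(x, 0, 0), U = diag(0.015, 3)),
    list(label = "H2", element = "H", frac = c(-x, 0, 0), U = diag(0.015, 3))))
  hkl <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 1, 0), c(-3, -1, 0))
  tab <- build_tsc(st2, hkl, n = 1)
  Fh <- structure_factor(st2, tab)
  # identical atoms at +/- (x,0,0): F = 2 f cos(2 pi h x) T(h)
  s_cart <- hkl_to_cart(cell, hkl)
  for (i in 1:2) {
    f_sph <- slater_form_factor(1, sqrt(sum(s_cart[i, ]^2)))
    dw <- exp(-2 * pi^2 * 0.015 * sum(s_cart[i, ]^2))
    expect_equal(Re(Fh[i]), 2 * f_sph * dw * cos(2 * pi * hkl[i, 1] * x),
                 tolerance = 1e-4)
    expect_lt(abs(Im(Fh[i])), 1e-8)
  }
  # Friedel pair
  expect_equal(Fh[4], Conj(Fh[3]), tolerance = 1e-10)
  # single atom at origin with U = 0 reproduces its form factor
  st1 <- toy_structure(cell, list(list(label = "H1", element = "H",
                                       frac = c(0, 0, 0),
                                       U = diag(0, 3))))
  tab1 <- build_tsc(st1, hkl)
  F1 <- structure_factor(st1, tab1)
  expect_equal(F1, tab1$values[1, ], tolerance = 1e-12)
  expect_error(structure_factor(st1, tab1, rbind(c(9, 9, 9))),
               "no form factors")
})

test_that("SHELX weights follow the quoted formula with both P conventions", {
  expect_equal(shelx_weight(4, 0.1, 3), 1 / 0.01)
  # a = 0.1, b = 0, literal P = 2*3 + 4 = 10
  expect_equal(shelx_weight(4, 0.1, 3, a = 0.1), 1 / (0.01 + 1))
  # standard convention divides P by 3
  expect_equal(shelx_weight(4, 0.1, 3, a = 0.1, p_convention = "standard"),
               1 / (0.01 + (0.1 * 10 / 3)^2))
  # negative Fo^2 is clamped inside P
  expect_equal(shelx_weight(-1, 0.5, 3, b = 2), 1 / (0.25 + 2 * 6))
  expect_error(shelx_weight(4, 0, 3), "sigma")
  expect_error(shelx_weight(4, 0.1, 3, a = -1), ">= 0")
})

test_that("agreement statistics match direct arithmetic", {
  cell <- unit_cell(5, 5, 5)
  dat <- reflection_data(rbind(c(1, 0, 0)), 4, 0.1, cell)
  st <- agreement_stats(dat, 1, 1)
  expect_equal(st$wr2, 3 / 4)
  expect_equal(st$r1, (2 - 1) / 2)
  # perfect fit
  dat2 <- reflection_data(rbind(c(1, 0, 0), c(0, 1, 0)), c(4, 9), c(1, 1),
                          cell)
  st2 <- agreement_stats(dat2, c(4, 9), c(1, 1))
  expect_equal(st2$r1, 0)
  expect_equal(st2$wr2, 0)
  # random small set vs spreadsheet-style sums
  set.seed(14)
  fo2 <- stats::runif(6, 1, 10); fc2 <- fo2 * stats::runif(6, 0.9, 1.1)
  w <- stats::runif(6, 0.5, 2)
  dat3 <- reflection_data(cbind(1:6, 0, 0), fo2, rep(0.1, 6), cell)
  st3 <- agreement_stats(dat3, fc2, w)
  expect_equal(st3$wr2, sqrt(sum(w * (fo2 - fc2)^2) / sum(w * fo2^2)))
  expect_equal(st3$r1, sum(abs(sqrt(fo2) - sqrt(fc2))) / sum(sqrt(fo2)))
})

test_that("refinement is a fixed point at the generating truth", {
  toy <- local_toy
  dat <- simulate_intensities(toy$st, 1, 1.0, 0, 1, engine = toy$engine,
                              density_model = "promolecule")
  res <- refine(toy$st, dat, toy$provider,
                free = list(scale = TRUE, xyz = "H1", uij = "H1"))
  expect_true(res$converged)
  expect_lte(res$macro_cycles, 2)
  expect_lt(res$r1, 1e-8)
})

test_that("refinement recovers perturbed parameters on noise-free data", {
  toy <- local_toy
  dat <- simulate_intensities(toy$st, 1, 1.0, 0, 1, engine = toy$engine,
                              density_model = "promolecule")
  start <- toy$st
  start$sites[[2]]$frac <- start$sites[[2]]$frac +
    c(0.02, -0.015, 0.02) / 4.5          # ~0.02 angstrom
  start$sites[[2]]$U <- start$sites[[2]]$U * 1.2
  res <- refine(start, dat, toy$provider,
                free = list(scale = TRUE, xyz = "H1", uij = "H1"),
                scale0 = 1.05)
  expect_true(res$converged)
  expect_lte(res$macro_cycles, 5)
  expect_lt(max(abs(res$structure$sites[[2]]$frac - toy$st$sites[[2]]$frac)),
            1e-4)
  expect_lt(max(abs(res$structure$sites[[2]]$U - toy$st$sites[[2]]$U)), 1e-4)
  expect_equal(res$scale, 1, tolerance = 1e-4)
  # tidy/glance interfaces
  td <- tidy(res)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(nrow(td), 10)
  expect_true(glance(res)$converged)
})

test_that("finite-difference gradients are consistent across step sizes", {
  toy <- local_toy
  dat <- simulate_intensities(toy$st, 1, 1.0, 0, 1, engine = toy$engine,
                              density_model = "promolecule")
  tab <- toy$provider(toy$st)
  fc2_of <- function(st, sc) Mod(structure_factor(st, tab, as.matrix(
    dat[, c("h", "k", "l")]), sc))^2
  st <- toy$st
  # derivative wrt U11 of H at two step sizes
  d_of <- function(h0) {
    stp <- st; stm <- st
    stp$sites[[2]]$U[1, 1] <- st$sites[[2]]$U[1, 1] + h0
    stm$sites[[2]]$U[1, 1] <- st$sites[[2]]$U[1, 1] - h0
    (fc2_of(stp, 1) - fc2_of(stm, 1)) / (2 * h0)
  }
  g1 <- d_of(1e-5); g2 <- d_of(1e-6)
  expect_lt(max(abs(g1 - g2)) / max(abs(g1)), 1e-5)
})

test_that("resolution cutoff is honoured exactly", {
  st <- make_structure("diatomic_XH", 1)
  for (d_min in c(0.8, 1.1)) {
    dat <- simulate_intensities(st, 1, d_min, 0, 1)
    expect_true(all(dat$d >= d_min))
    expect_equal(nrow(dat), nrow(generate_hkl(st$cell, d_min)))
  }
})

test_that("rank-deficient parameterizations are reported with the null-space parameters", {
  toy <- local_toy
  dat <- simulate_intensities(toy$st, 1, 1.0, 0, 1, engine = toy$engine,
                              density_model = "promolecule")
  # freeing both positions leaves the P1 floating origin undetermined
  expect_error(
    refine(toy$st, dat, toy$provider,
           free = list(scale = TRUE, xyz = c("X1", "H1"),
                       uij = character())),
    "singular normal matrix")
})

test_that("simulated intensities are deterministic per seed and exact when noise-free", {
  st <- make_structure("diatomic_XH", 1)
  d0 <- simulate_intensities(st, 1, 1.2, 0, 1)
  hkl <- generate_hkl(st$cell, 1.2)
  tab <- build_tsc(st, hkl, n = 1,
                   total = structure_total_density(st, "promolecule"))
  expect_equal(d0$f_obs_sq, Mod(structure_factor(st, tab))^2,
               tolerance = 1e-12)
  n1 <- simulate_intensities(st, 1, 1.2, 0.05, 7)
  n2 <- simulate_intensities(st, 1, 1.2, 0.05, 7)
  n3 <- simulate_intensities(st, 1, 1.2, 0.05, 8)
  expect_identical(n1$f_obs_sq, n2$f_obs_sq)
  expect_false(identical(n1$f_obs_sq, n3$f_obs_sq))
  expect_true(all(n1$sigma > 0))
})
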