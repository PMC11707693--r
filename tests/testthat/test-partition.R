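test_that("stockholder weights are a proper partition of unity", {
  fx <- h2plus_fixture(R = 2)
  set.seed(42)
  pts <- matrix(stats::rnorm(3000, sd = 2), ncol = 3)
  for (n in c(1, 2, 4)) {
    w <- stockholder_weights(partition_spec(fx$sites, n), pts)
    expect_true(all(w >= 0 & w <= 1))
    expect_lt(max(abs(rowSums(w) - 1)), 1e-12)
  }
  # single site: weight 1 everywhere
  one <- partition_spec(place_sites(list(slater_density("H")),
                                    matrix(0, 1, 3)), n = 3)
  expect_equal(drop(stockholder_weights(one, pts)), rep(1, nrow(pts)))
  # symmetry: bisector plane splits 50/50 for any n
  for (n in c(1, 1.7, 5)) {
    w <- stockholder_weights(partition_spec(fx$sites, n),
                             rbind(c(0, 0.7, -1.2)))
    expect_equal(w[1, 1], 0.5, tolerance = 1e-12)
  }
})

test_that("n = 1 reproduces the classic Hirshfeld ratio and large n the dominance limit", {
  fx <- h2plus_fixture(R = 2)
  set.seed(7)
  pts <- matrix(stats::rnorm(300, sd = 2), ncol = 3)
  w1 <- stockholder_weights(partition_spec(fx$sites, 1), pts)
  rhoA <- fx$sites[[1]]$density$evaluate(
    sqrt(rowSums(sweep(pts, 2, fx$sites[[1]]$position)^2)))
  rhoB <- fx$sites[[2]]$density$evaluate(
    sqrt(rowSums(sweep(pts, 2, fx$sites[[2]]$position)^2)))
  expect_equal(w1[, 1], rhoA / (rhoA + rhoB), tolerance = 1e-12)
  # n = 64: a point strictly nearer A in promolecule terms is all A's
  w64 <- stockholder_weights(partition_spec(fx$sites, 64), c(-0.8, 0, 0))
  expect_gt(w64[1, 1], 0.999)
})

test_that("weights are monotone in n where one atom dominates", {
  fx <- h2plus_fixture(R = 2)
  set.seed(11)
  pts <- matrix(stats::rnorm(150, sd = 1.5), ncol = 3)
  ns <- c(1, 1.25, 1.5, 2, 3, 4)
  w_by_n <- lapply(ns, function(n)
    stockholder_weights(partition_spec(fx$sites, n), pts))
  rhoA <- fx$sites[[1]]$density$evaluate(
    sqrt(rowSums(sweep(pts, 2, fx$sites[[1]]$position)^2)))
  rhoB <- fx$sites[[2]]$density$evaluate(
    sqrt(rowSums(sweep(pts, 2, fx$sites[[2]]$position)^2)))
  dominant_A <- rhoA > rhoB
  for (k in seq_len(length(ns) - 1)) {
    expect_true(all(
      w_by_n[[k + 1]][dominant_A, 1] >= w_by_n[[k]][dominant_A, 1] - 1e-12))
  }
})

test_that("partitioned atomic densities sum to the total density exactly", {
  fx <- h2plus_fixture(R = 2)
  set.seed(3)
  pts <- matrix(stats::rnorm(30, sd = 1.5), ncol = 3)
  for (n in c(1, 2.5, 4)) {
    spec <- partition_spec(fx$sites, n)
    m <- partitioned_atomic_density(spec, fx$total, pts)
    expect_equal(rowSums(m), fx$total$evaluate(pts), tolerance = 1e-14)
  }
  # between the nuclei, larger n gives the nearer atom a larger share
  p_near_A <- c(-0.5, 0, 0)
  d1 <- partitioned_atomic_density(partition_spec(fx$sites, 1), fx$total,
                                   p_near_A, 1)
  d4 <- partitioned_atomic_density(partition_spec(fx$sites, 4), fx$total,
                                   p_near_A, 1)
  expect_gt(d4, d1)
})

test_that("far-field points fall back to nearest-site weights, never NaN", {
  fx <- h2plus_fixture(R = 2)
  w <- stockholder_weights(partition_spec(fx$sites, 2), c(-800, 0, 0))
  expect_false(anyNA(w))
  expect_equal(w[1, ], c(1, 0))
})

test_that("H2+-like charges are +0.5 each and conserved for every exponent", {
  fx <- h2plus_fixture(R = 2)
  for (n in c(1, 2, 4)) {
    ch <- atomic_charge(partition_spec(fx$sites, n), fx$total,
                        z = c(1, 1))
    expect_equal(ch$charge, c(0.5, 0.5), tolerance = 1e-4)
  }
})

test_that("heteronuclear charges are conserved and grow in magnitude with the exponent", {
  # charge conservation on the bonding X-H toy (zeta_X != zeta_H)
  fx <- xh_fixture()
  for (n in c(1, 2)) {
    spec <- structure_partition_spec(fx$structure, n)
    ch <- atomic_charge(spec, fx$total, sgrid = sphere_grid(974),
                        rgrid = radial_grid(100))
    expect_equal(sum(ch$charge), 0, tolerance = 1e-4,
                 label = paste("charge sum at n =", n))
  }
  # magnitude trend on a heteronuclear promolecule-total toy: the n = 1
  # stockholder shares reproduce the isolated atoms (zero charges); any
  # larger exponent moves charge between the unlike atoms
  dens <- list(slater_density("A", zeta = 1.6, electron_count = 2),
               slater_density("B", zeta = 1.0, electron_count = 1))
  sites <- place_sites(dens, rbind(c(0, 0, 0), c(1.9, 0, 0)))
  tot <- promolecule_as_molecular(sites)
  q1 <- atomic_charge(partition_spec(sites, 1), tot)
  q2 <- atomic_charge(partition_spec(sites, 2), tot)
  expect_equal(q1$charge[1], 0, tolerance = 1e-4)
  expect_gte(abs(q2$charge[1]) + 1e-6, abs(q1$charge[1]))
  expect_gt(abs(q2$charge[1]), 1e-3)
})

test_that("overlap coefficient is symmetric, decaying, and decreasing in n", {
  fx <- h2plus_fixture(R = 2)
  for (def in c("min", "product")) {
    o <- sapply(c(1, 2, 4), function(n)
      overlap_coefficient(partition_spec(fx$sites, n), fx$total, 1, 2,
                          definition = def))
    expect_true(all(o >= 0 & o <= 1))
    expect_true(all(diff(o) < 0), label = paste("monotone decay for", def))
  }
  # symmetry on a heteronuclear pair
  het <- xh_fixture()
  spec <- het$spec1
  o_ab <- overlap_coefficient(spec, het$total, 1, 2)
  o_ba <- overlap_coefficient(spec, het$total, 2, 1)
  expect_equal(o_ab, o_ba, tolerance = 1e-10)
  # infinitely separated pair
  far <- partition_spec(place_sites(
    list(slater_density("H", zeta = 1, electron_count = 1),
         slater_density("H", zeta = 1, electron_count = 1)),
    rbind(c(-25, 0, 0), c(25, 0, 0))), 1)
  far_tot <- promolecule_as_molecular(far$sites)
  expect_lt(overlap_coefficient(far, far_tot, 1, 2), 1e-10)
  expect_error(
    overlap_coefficient(spec, het$total, 1, 2, definition = "fancy"),
    "unknown overlap definition")
})
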