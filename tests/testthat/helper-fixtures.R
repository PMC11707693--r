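# shared toy fixtures, built in code at test time

# symmetric H2+-like pair: two unit-zeta hydrogen 1s promolecule sites R bohr
# apart on the x axis, with the one-electron two-centre density as total
h2plus_fixture <- function(R = 2) {
  sites <- place_sites(
    list(slater_density("H", zeta = 1, electron_count = 1),
         slater_density("H", zeta = 1, electron_count = 1)),
    rbind(c(-R / 2, 0, 0), c(R / 2, 0, 0)))
  total <- molecular_density(function(p) toy_two_center_density(R, p), 1, sites)
  list(sites = sites, total = total, R = R)
}

# heteronuclear toy: compact X (7 e) and H (1 e), bonding total density
xh_fixture <- function(seed = 1) {
  st <- make_structure("diatomic_XH", seed)
  list(structure = st,
       spec1 = structure_partition_spec(st, 1),
       total = structure_total_density(st, "bonding"))
}

# physically plausible random ADP: random orientation, principal MSDs
# uniform in [0.01, 0.05] angstrom^2 (axis ratios a few to one, as for
# real thermal ellipsoids)
random_spd <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  ev <- stats::runif(3, 0.01, 0.05)
  Q %*% diag(ev) %*% t(Q)
}
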