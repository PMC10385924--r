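# Build a molecule snapshot directly from coordinates, bonds, masses and
# charges, going through the package's own topology builder.
snap_from <- function(coords, bonds, masses, charges = rep(0, nrow(coords)),
                      timestep = 0L) {
  n <- nrow(coords)
  u_mass <- unique(masses)
  data <- structure(list(
    masses = data.frame(type = seq_along(u_mass), mass = u_mass),
    atoms = data.frame(id = seq_len(n), mol = 1L,
                       type = match(masses, u_mass), q = charges,
                       x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    bonds = if (nrow(bonds)) {
      data.frame(id = seq_len(nrow(bonds)), type = 1L,
                 i = bonds[, 1], j = bonds[, 2])
    } else data.frame(id = integer(0), type = integer(0),
                      i = integer(0), j = integer(0)),
    box = matrix(c(0, 0, 0, 100, 100, 100), 3, 2,
                 dimnames = list(c("x", "y", "z"), c("lo", "hi")))
  ), class = "lammps_data")
  topo <- build_topology(data)
  trajdescr:::molecule_snapshot(topo$molecules[[1]], coords, topo, timestep)
}

# snapshot of a seeded random-walk carbon chain
chain_snapshot <- function(n, seed = 1, bond_length = 1.54,
                           charges = NULL) {
  tpl <- template_chain(n, bond_length, seed)
  if (is.null(charges)) charges <- tpl$charges
  snap_from(tpl$coords, tpl$bonds, tpl$masses, charges)
}

# heterogeneous snapshot: random-walk chain with mixed elements/charges
hetero_snapshot <- function(n, seed = 1) {
  tpl <- template_chain(n, 1.5, seed)
  set.seed(seed + 1000)
  masses <- sample(c(12.011, 15.999, 14.007, 1.008, 32.06), n,
                   replace = TRUE)
  charges <- round(stats::runif(n, -0.5, 0.5), 3)
  snap_from(tpl$coords, tpl$bonds, masses, charges)
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(x)), label = "all values finite")
}
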