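test_that("element inference maps masses to elements and UA pseudo-atoms", {
  expect_equal(infer_element(12.011), "C")
  expect_equal(infer_element(1.008), "H")
  expect_equal(infer_element(15.999), "O")
  expect_equal(infer_element(15.035), "CH3")
  expect_equal(infer_element(14.027), "CH2")
  expect_equal(infer_element(14.007), "N")  # distinct from CH2 at 14.027
  expect_equal(infer_element(13.019), "CH")
  expect_error(infer_element(6.5), "UnknownMass")
})

test_that("UA pseudo-elements take carbon properties but keep their mass", {
  tab <- property_table()
  c_row <- tab[tab$element == "C", ]
  ch3 <- tab[tab$element == "CH3", ]
  expect_equal(ch3$vdw_radius, c_row$vdw_radius)
  expect_equal(ch3$electronegativity, c_row$electronegativity)
  expect_equal(ch3$mass, 15.035)
})

test_that("topological distances follow the bond graph", {
  # 4-atom path: d(1,4) = 3
  coords <- cbind(0:3, 0, 0)
  snap <- snap_from(coords, cbind(1:3, 2:4), rep(12.011, 4))
  expect_equal(snap$d_top[1, 4], 3)
  expect_equal(snap$d_top[2, 3], 1)
  expect_true(isSymmetric(snap$d_top))
  expect_equal(diag(snap$d_top), rep(0, 4))
})

test_that("topological distances match a Floyd-Warshall oracle", {
  for (seed in c(3, 17)) {
    tpl <- template_chain(12, seed = seed)
    # add two extra cross-links to make a cyclic graph
    bonds <- rbind(tpl$bonds, c(1, 6), c(4, 11))
    snap <- snap_from(tpl$coords, bonds, tpl$masses)
    n <- 12
    D <- matrix(Inf, n, n); diag(D) <- 0
    for (b in seq_len(nrow(bonds))) {
      D[bonds[b, 1], bonds[b, 2]] <- 1
      D[bonds[b, 2], bonds[b, 1]] <- 1
    }
    for (k in 1:n) for (i in 1:n) for (j in 1:n) {
      if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    }
    expect_equal(snap$d_top, D)
  }
})

test_that("cross-molecule bonds and disconnected molecules are rejected", {
  data <- structure(list(
    masses = data.frame(type = 1L, mass = 12.011),
    atoms = data.frame(id = 1:4, mol = c(3L, 3L, 4L, 4L), type = 1L, q = 0,
                       x = c(0, 1, 5, 6), y = 0, z = 0),
    bonds = data.frame(id = 1:2, type = 1L, i = c(1L, 2L), j = c(2L, 3L)),
    box = matrix(c(0, 0, 0, 10, 10, 10), 3, 2,
                 dimnames = list(c("x", "y", "z"), c("lo", "hi")))
  ), class = "lammps_data")
  expect_error(build_topology(data), "DisconnectedMolecule")
})

test_that("minimum-image unwrapping recovers the analytic separation", {
  data <- structure(list(
    masses = data.frame(type = 1L, mass = 12.011),
    atoms = data.frame(id = 1:2, mol = 1L, type = 1L, q = 0,
                       x = c(0.5, 9.8), y = 1, z = 1),
    bonds = data.frame(id = 1L, type = 1L, i = 1L, j = 2L),
    box = matrix(c(0, 0, 0, 10, 10, 10), 3, 2,
                 dimnames = list(c("x", "y", "z"), c("lo", "hi")))
  ), class = "lammps_data")
  topo <- build_topology(data)
  frame <- list(timestep = 0L, box = data$box, periodic = rep(TRUE, 3),
                coord_kind = "wrapped",
                atoms = data$atoms[c("id", "mol", "type", "x", "y", "z")])
  un <- unwrap_frame(frame, topo)
  expect_equal(abs(un[["1"]][2, 1] - un[["1"]][1, 1]), 0.7, tolerance = 1e-12)
})

test_that("already-unwrapped frames pass through unchanged", {
  spec <- fixture_spec(template_chain(8, seed = 4), copies = 1,
                       frames = 1, wrap = FALSE, seed = 6)
  fx <- generate_fixture(spec)
  topo <- build_topology(parse_data(fx$data_path))
  frame <- parse_dump(fx$dump_path)[[1]]
  un <- unwrap_frame(frame, topo)
  expect_equal(unname(un[["1"]]), unname(fx$truth$frames[[1]]))
})

test_that("wrapping then unwrapping reproduces ground-truth geometry", {
  # 20-atom chain crossing a corner of a 15 A box
  spec <- fixture_spec(template_chain(20, bond_length = 1.54, seed = 21),
                       copies = 1, box = c(15, 15, 15), frames = 2,
                       wrap = TRUE, seed = 8)
  fx <- generate_fixture(spec)
  topo <- build_topology(parse_data(fx$data_path))
  frames <- parse_dump(fx$dump_path)
  for (f in seq_along(frames)) {
    expect_equal(frames[[f]]$coord_kind, "wrapped")
    un <- unwrap_frame(frames[[f]], topo)[["1"]]
    truth <- fx$truth$frames[[f]]
    # bond lengths recovered exactly
    dl_un <- sqrt(rowSums((un[1:19, ] - un[2:20, ])^2))
    dl_tr <- sqrt(rowSums((truth[1:19, ] - truth[2:20, ])^2))
    expect_equal(dl_un, dl_tr, tolerance = 1e-9, ignore_attr = TRUE)
    # full pairwise distances match up to a lattice translation
    expect_equal(as.matrix(dist(un)), as.matrix(dist(truth)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    shift <- (un - truth)[1, ]
    expect_equal(shift - round(shift / 15) * 15, rep(0, 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("unwrapping is idempotent", {
  spec <- fixture_spec(template_chain(10, seed = 5), copies = 1,
                       box = c(12, 12, 12), wrap = TRUE, seed = 2)
  fx <- generate_fixture(spec)
  topo <- build_topology(parse_data(fx$data_path))
  frame <- parse_dump(fx$dump_path)[[1]]
  un1 <- unwrap_frame(frame, topo)
  frame2 <- frame
  frame2$coord_kind <- "unwrapped"
  frame2$atoms[c("x", "y", "z")] <- un1[["1"]]
  un2 <- unwrap_frame(frame2, topo)
  expect_equal(un1[["1"]], un2[["1"]], ignore_attr = TRUE)
})

test_that("bonds longer than half the box are refused, not guessed", {
  data <- structure(list(
    masses = data.frame(type = 1L, mass = 12.011),
    atoms = data.frame(id = 1:2, mol = 1L, type = 1L, q = 0,
                       x = c(0.0, 3.9), y = 0, z = 0),
    bonds = data.frame(id = 1L, type = 1L, i = 1L, j = 2L),
    box = matrix(c(0, 0, 0, 8, 8, 8), 3, 2,
                 dimnames = list(c("x", "y", "z"), c("lo", "hi")))
  ), class = "lammps_data")
  topo <- build_topology(data)
  frame <- list(timestep = 0L, box = data$box, periodic = rep(TRUE, 3),
                coord_kind = "wrapped",
                atoms = data$atoms[c("id", "mol", "type", "x", "y", "z")])
  expect_error(unwrap_frame(frame, topo), "BondLongerThanHalfBox")
})

test_that("geometry matrices match a brute-force double loop", {
  expect_equal(geometry_matrices(rbind(c(0, 0, 0), c(3, 4, 0)))$dist[1, 2], 5)
  expect_equal(geometry_matrices(matrix(c(1, 2, 3), 1))$dist,
               matrix(0, 1, 1))

  set.seed(42)
  X <- matrix(rnorm(30), 10, 3)
  gm <- geometry_matrices(X)
  D <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  expect_equal(gm$dist, D, tolerance = 1e-12)
  expect_equal(colSums(gm$centered), rep(0, 3), tolerance = 1e-9)
})
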