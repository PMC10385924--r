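test_that("dipole moment matches the closed form and its symmetries", {
  X <- rbind(c(1, 0, 0), c(0, 0, 0))
  expect_equal(dipole_moment(X, c(0.5, -0.5), c(1, 1)), 0.5 * 4.8032)
  expect_equal(dipole_moment(X, c(0, 0), c(1, 1)), 0)
  # mirrored +-q pairs cancel
  X4 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 2, 0), c(0, -2, 0))
  expect_equal(dipole_moment(X4, c(0.3, 0.3, -0.3, -0.3), rep(1, 4)), 0)
})

test_that("inertia and gyration shape set match hand values and an oracle", {
  # two unit masses at (+-1, 0, 0): Rg = 1
  s <- snap_from(rbind(c(-1, 0, 0), c(1, 0, 0)), cbind(1L, 2L),
                 rep(12.011, 2))
  g <- geometric_block(s)
  expect_equal(unname(g["Rg"]), 1)
  expect_equal(unname(g["kappa2"]), 1)  # perfect rod

  # a rod is perfectly cylindrical: the two transverse eigenvalues tie
  rod <- snap_from(cbind(0:3, 0, 0), cbind(1:3, 2:4), rep(12.011, 4))
  expect_equal(unname(geometric_block(rod)["acylindricity"]), 0,
               tolerance = 1e-12)
  # square of unit masses: transverse eigenvalues (0, 1) differ
  sq <- snap_from(rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)),
                  cbind(1:3, 2:4), rep(12.011, 4))
  expect_equal(unname(geometric_block(sq)["acylindricity"]), 1,
               tolerance = 1e-12)

  # random 12-atom configuration vs brute-force eigendecomposition
  set.seed(99)
  X <- matrix(rnorm(36, sd = 2), 12, 3)
  m <- runif(12, 1, 16)
  s12 <- snap_from(X, cbind(1:11, 2:12), rep(12.011, 12))
  s12$mass <- m  # arbitrary masses for the oracle comparison
  g12 <- geometric_block(s12)
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  It <- matrix(0, 3, 3)
  for (i in 1:12) {
    r <- Xc[i, ]
    It <- It + m[i] * (diag(sum(r^2), 3) - outer(r, r))
  }
  expect_equal(unname(g12[c("I1", "I2", "I3")]),
               sort(eigen(It)$values), tolerance = 1e-10)
  Sg <- matrix(0, 3, 3)
  for (i in 1:12) Sg <- Sg + m[i] * outer(Xc[i, ], Xc[i, ])
  Sg <- Sg / sum(m)
  expect_equal(unname(g12["Rg"]), sqrt(sum(eigen(Sg)$values)),
               tolerance = 1e-10)
})

test_that("gravitation indices split into bonded and non-bonded parts", {
  s <- snap_from(rbind(c(0, 0, 0), c(2, 0, 0)), cbind(1L, 2L),
                 c(12.011, 15.999))
  s$mass <- c(12, 16)
  g <- geometric_block(s)
  expect_equal(unname(g["grav1"]), 12 * 16 / 4)
  expect_equal(unname(g["grav2"]), 12 * 16 / 4)

  # 3-atom chain: grav1 - grav2 = the single non-bonded pair
  X <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0))
  s3 <- snap_from(X, cbind(1:2, 2:3), rep(12.011, 3))
  s3$mass <- c(12, 12, 16)
  g3 <- geometric_block(s3)
  r13 <- sqrt(sum((X[1, ] - X[3, ])^2))
  expect_equal(unname(g3["grav1"] - g3["grav2"]), 12 * 16 / r13^2,
               tolerance = 1e-12)
})

test_that("molecular volume approaches analytic sphere volumes", {
  one <- mol_volume(matrix(0, 1, 3), 1.7)
  expect_equal(one, (4 / 3) * pi * 1.7^3, tolerance = 0.02)
  two_far <- mol_volume(rbind(c(0, 0, 0), c(10, 0, 0)), c(1.7, 1.7))
  expect_equal(two_far, 2 * one, tolerance = 0.02)
  two_same <- mol_volume(rbind(c(0, 0, 0), c(0, 0, 0)), c(1.7, 1.7))
  expect_equal(two_same, one)
  # monotone in the radius
  expect_gt(mol_volume(matrix(0, 1, 3), 1.9), one)
})

test_that("shadow indices match the analytic disk and are frame-invariant", {
  s1 <- shadow_indices(matrix(0, 1, 3), 12, 1.7)
  expect_equal(unname(s1[1:3]), rep(pi * 1.7^2, 3), tolerance = 0.02)
  expect_equal(unname(s1[4:6]), rep(pi / 4, 3), tolerance = 0.02)

  two <- shadow_indices(rbind(c(0, 0, 0), c(0, 0, 0)), c(6, 6), c(1.7, 1.7))
  expect_equal(unname(two), unname(s1), tolerance = 1e-9)

  tpl <- template_chain(10, seed = 44)
  a <- shadow_indices(tpl$coords, tpl$masses, rep(1.7, 10))
  X2 <- rigid_motion(tpl$coords, random_rotation(9), c(5, 5, 5))
  b <- shadow_indices(X2, tpl$masses, rep(1.7, 10))
  expect_equal(a, b, tolerance = 0.02)
})

test_that("plane of best fit is zero for planar sets and matches a numeric
          minimiser for a tetrahedron", {
  ring <- template_ring(6)
  expect_equal(pbf_score(ring$coords), 0, tolerance = 1e-12)
  expect_equal(pbf_score(rbind(c(0, 0, 0), c(1, 1, 1))), 0)

  a <- 1.5
  tet <- rbind(c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a)) / sqrt(3)
  got <- pbf_score(tet)
  # brute-force minimisation of the mean |distance| over plane orientations
  obj <- function(ang) {
    n <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    Xc <- sweep(tet, 2, colMeans(tet))
    mean(abs(Xc %*% n))
  }
  grid <- expand.grid(t1 = seq(0, pi, length.out = 40),
                      t2 = seq(0, 2 * pi, length.out = 80))
  vals <- apply(grid, 1, obj)
  best <- Inf
  for (i in order(vals)[1:12]) {
    o <- optim(as.numeric(grid[i, ]), obj)$value
    if (o < best) best <- o
  }
  expect_lte(got - best, 1e-6)
  expect_equal(got, best, tolerance = 1e-4)
})

test_that("chain measures on a straight chain are fully extended", {
  X <- cbind(0:4, 0, 0)
  s <- snap_from(X, cbind(1:4, 2:5), rep(12.011, 5))
  cm <- chain_measures(s)
  expect_equal(unname(cm["Ree"]), 4)
  expect_equal(unname(cm["Lcontour"]), 4)
  expect_equal(unname(cm["lk"]), 4)
  expect_equal(unname(cm[paste0("phi", 1:4)]), rep(1, 4))
  expect_equal(unname(cm[paste0("phi", 5:10)]), rep(0, 6))  # m < k
})

test_that("a chain folded onto itself has zero end-to-end and Kuhn length", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  s <- snap_from(X, cbind(1:4, 2:5), rep(12.011, 5))
  cm <- chain_measures(s)
  expect_equal(unname(cm["Ree"]), 0)
  expect_equal(unname(cm["lk"]), 0)
})

test_that("phi4 matches a brute-force windowed ratio on a random walk", {
  tpl <- template_chain(20, seed = 77)
  s <- snap_from(tpl$coords, tpl$bonds, tpl$masses)
  cm <- chain_measures(s)
  X <- tpl$coords
  blen <- sqrt(rowSums((X[1:19, ] - X[2:20, ])^2))
  k <- 4
  ratios <- sapply(1:(19 - k + 1), function(i) {
    sqrt(sum((X[i, ] - X[i + k, ])^2)) / sum(blen[i:(i + k - 1)])
  })
  expect_equal(unname(cm["phi4"]), mean(ratios), tolerance = 1e-12)
  expect_true(all(cm[paste0("phi", 1:10)] <= 1 + 1e-12))
})

test_that("the geometric block is invariant under rigid motion", {
  tpl <- template_chain(10, seed = 5)
  charges <- rep(c(0.1, -0.1), 5)
  s0 <- snap_from(tpl$coords, tpl$bonds, tpl$masses, charges)
  g0 <- geometric_block(s0)
  X2 <- rigid_motion(tpl$coords, random_rotation(31), c(-4, 2, 9))
  g2 <- geometric_block(snap_from(X2, tpl$bonds, tpl$masses, charges))
  grid_based <- c("molvolume", paste0("S", 1:6))
  exact <- setdiff(names(g0), grid_based)
  expect_equal(g0[exact], g2[exact], tolerance = 1e-9)
  expect_equal(g0[grid_based], g2[grid_based], tolerance = 0.02)
})
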