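make_frame <- function(box_len, atoms) {
  list(timestep = 0L,
       box = matrix(c(0, 0, 0, box_len), 3, 2,
                    dimnames = list(c("x", "y", "z"), c("lo", "hi"))),
       periodic = rep(TRUE, 3), coord_kind = "unwrapped", atoms = atoms)
}

test_that("density follows the closed form and the volume scaling law", {
  # total mass 602.2 g/mol in a 1000 A^3 box -> 1.0000 g/cm^3
  data <- structure(list(
    masses = data.frame(type = 1L, mass = 301.1),
    atoms = data.frame(id = 1:2, mol = 1L, type = 1L, q = 0,
                       x = c(1, 2), y = 1, z = 1),
    bonds = data.frame(id = 1L, type = 1L, i = 1L, j = 2L),
    box = matrix(c(0, 0, 0, 10, 10, 10), 3, 2,
                 dimnames = list(c("x", "y", "z"), c("lo", "hi")))
  ), class = "lammps_data")
  # 301.1 is no element: force the masses through directly
  topo <- list(atoms = data.frame(mass = c(301.1, 301.1)))
  f1 <- make_frame(c(10, 10, 10), data$atoms)
  f1$box <- data$box
  expect_equal(system_density(f1, topo), 1.0000, tolerance = 1e-4)

  f2 <- f1
  f2$box[, "hi"] <- 20  # double every side: density / 8
  expect_equal(system_density(f2, topo), system_density(f1, topo) / 8)

  topo0 <- list(atoms = data.frame(mass = numeric(0)))
  expect_equal(system_density(f1, topo0), 0)
})

test_that("the run writes one CSV per molecule with one row per frame", {
  spec <- fixture_spec(template_chain(8, seed = 12), copies = 2,
                       frames = 3, box = c(25, 25, 25), seed = 40,
                       mol_ids = c(3L, 7L))
  fx <- generate_fixture(spec)
  out <- file.path(tempdir(), "run-naming")
  paths <- run_descriptors(fx$data_path, fx$dump_path, out, sets = c(1, 4),
                           workers = 1, quiet = TRUE)
  expect_setequal(basename(paths), c("molecule_3.csv", "molecule_7.csv"))
  expect_true(all(file.exists(paths)))
  d <- read.csv(paths[1], check.names = FALSE)
  expect_equal(nrow(d), 3)
  expect_equal(d$timestep, 0:2)
  expect_true(file.exists(file.path(out, "manifest.json")))
})

test_that("set selection controls exactly which columns appear", {
  spec <- fixture_spec(template_chain(10, seed = 2), copies = 1,
                       frames = 1, seed = 1)
  fx <- generate_fixture(spec)
  out4 <- file.path(tempdir(), "run-set4")
  p4 <- run_descriptors(fx$data_path, fx$dump_path, out4, sets = 4,
                        workers = 1, quiet = TRUE)
  d4 <- read.csv(p4[1], check.names = FALSE)
  expect_equal(names(d4), c("timestep", "density", cpsa_names()))
  expect_equal(ncol(d4), 2 + 30)

  out45 <- file.path(tempdir(), "run-set45")
  p45 <- run_descriptors(fx$data_path, fx$dump_path, out45, sets = c(5, 4),
                         workers = 1, quiet = TRUE)
  d45 <- read.csv(p45[1], check.names = FALSE)
  # union of the single-set runs, in fixed set order
  expect_equal(names(d45), c("timestep", "density", cpsa_names(),
                             whim_names()))
})

test_that("worker counts and reruns give byte-identical output", {
  spec <- fixture_spec(template_chain(9, seed = 6), copies = 2,
                       frames = 2, seed = 14)
  fx <- generate_fixture(spec)
  outs <- file.path(tempdir(), paste0("run-det-", 1:3))
  for (i in 1:3) {
    run_descriptors(fx$data_path, fx$dump_path, outs[i],
                    sets = c(2, 3, 6), workers = c(1, 4, 1)[i],
                    quiet = TRUE)
  }
  for (mol in c("molecule_1.csv", "molecule_2.csv")) {
    b1 <- readBin(file.path(outs[1], mol), "raw", 1e6)
    b2 <- readBin(file.path(outs[2], mol), "raw", 1e6)
    b3 <- readBin(file.path(outs[3], mol), "raw", 1e6)
    expect_identical(b1, b2)
    expect_identical(b1, b3)
  }
})

test_that("wrapped and unwrapped dumps of one system give identical CSVs", {
  tpl <- template_chain(12, seed = 9)
  for (wrap in c(FALSE, TRUE)) {
    spec <- fixture_spec(tpl, copies = 1, frames = 2, box = c(14, 14, 14),
                         wrap = wrap, seed = 77)
    fx <- generate_fixture(spec, dir = file.path(tempdir(),
                                                 paste0("wrapfx", wrap)))
    run_descriptors(fx$data_path, fx$dump_path,
                    file.path(tempdir(), paste0("run-wrap-", wrap)),
                    sets = c(1, 2, 5), workers = 1, quiet = TRUE)
  }
  a <- readLines(file.path(tempdir(), "run-wrap-FALSE", "molecule_1.csv"))
  b <- readLines(file.path(tempdir(), "run-wrap-TRUE", "molecule_1.csv"))
  expect_identical(a, b)
})

test_that("density is a system property, identical in every molecule CSV", {
  spec <- fixture_spec(template_methane(), copies = 3, frames = 2,
                       box = c(20, 20, 20), seed = 55)
  fx <- generate_fixture(spec)
  out <- file.path(tempdir(), "run-rho")
  paths <- run_descriptors(fx$data_path, fx$dump_path, out, sets = 4,
                           workers = 1, quiet = TRUE)
  rhos <- lapply(paths, function(p) read.csv(p)$density)
  expect_equal(rhos[[1]], rhos[[2]])
  expect_equal(rhos[[1]], rhos[[3]])
  # 3 methane molecules: 3 * 16.043 g/mol in 8000 A^3
  expect_equal(rhos[[1]][1], 3 * (12.011 + 4 * 1.008) * 1.66054 / 8000,
               tolerance = 1e-12)
})

test_that("shortest round-trip formatting survives read-back exactly", {
  x <- c(0, 1, -1.5, 1 / 3, exp(1), 1.66054e-7, 123456.789)
  s <- trajdescr:::format_shortest(x)
  expect_identical(as.numeric(s), x)
})
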