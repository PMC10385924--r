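#' Molecule templates for synthetic fixtures
#'
#' Constructed geometries with known ground truth, used to exercise the
#' parser, the unwrapping and every descriptor family without any external
#' data.  Available templates:
#' \describe{
#'   \item{\code{template_methane()}}{all-atom CH4, C-H = 1.09 Angstrom,
#'     tetrahedral; charges C = -0.4 e, H = +0.1 e.}
#'   \item{\code{template_alkane(n)}}{united-atom n-alkane: planar zig-zag
#'     of CH3/CH2 pseudo-atoms, C-C = 1.54 Angstrom, 114 degree backbone
#'     angle, zero charges.}
#'   \item{\code{template_chain(n, bond_length, seed)}}{freely jointed
#'     random-walk carbon chain with fixed bond length and seeded uniform
#'     random directions (self-overlap allowed).}
#'   \item{\code{template_ring(n)}}{planar regular carbon ring with
#'     1.4 Angstrom edges.}
#' }
#'
#' @param n Number of backbone atoms (chain/alkane/ring).
#' @param bond_length Bond length in Angstrom for the random-walk chain.
#' @param seed Integer seed for the random-walk directions.
#' @return A list with \code{coords} (N x 3), \code{masses} (per atom,
#'   g/mol), \code{charges} (e), \code{bonds} (2-column matrix of 1-based
#'   local indices).
#' @name fixture_templates
NULL

#' @rdname fixture_templates
#' @export
template_methane <- function() {
  a <- 1.09 / sqrt(3)
  coords <- rbind(c(0, 0, 0),
                  c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a))
  list(coords = coords,
       masses = c(12.011, rep(1.008, 4)),
       charges = c(-0.4, rep(0.1, 4)),
       bonds = cbind(1L, 2:5))
}

#' @rdname fixture_templates
#' @export
template_alkane <- function(n) {
  stopifnot(n >= 2)
  b <- 1.54; theta <- 114 * pi / 180
  # planar zig-zag: step along x, alternate +-z
  dx <- b * sin(theta / 2); dz <- b * cos(theta / 2)
  coords <- cbind(x = (seq_len(n) - 1) * dx,
                  y = 0,
                  z = ifelse(seq_len(n) %% 2 == 0, dz, 0))
  masses <- c(15.035, rep(14.027, max(0, n - 2)), 15.035)[seq_len(n)]
  if (n == 2) masses <- c(15.035, 15.035)
  list(coords = unname(coords), masses = masses,
       charges = rep(0, n),
       bonds = cbind(seq_len(n - 1), seq_len(n - 1) + 1L))
}

#' @rdname fixture_templates
#' @export
template_chain <- function(n, bond_length = 1.54, seed = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coords <- rbind(c(0, 0, 0), apply(dirs * bond_length, 2, cumsum))
  if (n == 2) coords <- rbind(c(0, 0, 0), dirs * bond_length)
  list(coords = unname(coords), masses = rep(12.011, n),
       charges = rep(0, n),
       bonds = cbind(seq_len(n - 1), seq_len(n - 1) + 1L))
}

#' @rdname fixture_templates
#' @export
template_ring <- function(n) {
  stopifnot(n >= 3)
  edge <- 1.4
  R <- edge / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  coords <- cbind(R * cos(ang), R * sin(ang), 0)
  list(coords = unname(coords), masses = rep(12.011, n),
       charges = rep(0, n),
       bonds = cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L)))
}

#' Uniformly random rotation matrix
#'
#' @param seed Integer seed.
#' @return 3 x 3 proper rotation matrix (determinant +1).
#' @export
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_d)
  d <- diag(qr.R(qr_d))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Apply a rigid motion to coordinates
#'
#' @param X N x 3 coordinates.
#' @param R 3 x 3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return Transformed N x 3 coordinates.
#' @export
rigid_motion <- function(X, R = diag(3), t = c(0, 0, 0)) {
  sweep(as.matrix(X) %*% t(R), 2, -t)
}

#' Specify a synthetic LAMMPS fixture
#'
#' Describes a small synthetic system: one molecule template, a number of
#' copies placed on a grid inside an orthogonal periodic box, a number of
#' frames each applying a seeded rigid motion per molecule, and whether the
#' dump should carry wrapped (\code{x y z}) or unwrapped (\code{xu yu zu})
#' coordinates.  All randomness is governed by \code{seed}, so generation
#' is byte-reproducible.
#'
#' @param template A template list (see \link{fixture_templates}).
#' @param copies Number of molecule copies.
#' @param box Length-3 box edge lengths in Angstrom.
#' @param frames Number of dump frames.
#' @param wrap Logical: write wrapped coordinates to the dump?
#' @param seed Integer seed for placements and per-frame motions.
#' @param mol_ids Optional molecule ids (default \code{1:copies}).
#' @param charges Optional per-atom charge override for one copy
#'   (recycled to all copies), e.g. an alternating +-q pattern.
#' @param rigid_per_frame Logical: apply a fresh random rotation +
#'   translation to each molecule at each frame after the first.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(template, copies = 1, box = c(30, 30, 30),
                         frames = 1, wrap = FALSE, seed = 1,
                         mol_ids = NULL, charges = NULL,
                         rigid_per_frame = TRUE) {
  stopifnot(copies >= 1, frames >= 1, length(box) == 3, all(box > 0))
  if (is.null(mol_ids)) mol_ids <- seq_len(copies)
  stopifnot(length(mol_ids) == copies)
  if (!is.null(charges)) {
    stopifnot(length(charges) == nrow(template$coords))
    template$charges <- charges
  }
  bl <- sqrt(rowSums((template$coords[template$bonds[, 1], , drop = FALSE] -
                      template$coords[template$bonds[, 2], , drop = FALSE])^2))
  if (length(bl) && max(bl) >= min(box) / 2) {
    stop("SpecInvalid: a bond length reaches half the shortest box side; ",
         "unwrapping would be ill-posed", call. = FALSE)
  }
  structure(list(template = template, copies = copies, box = box,
                 frames = frames, wrap = wrap, seed = seed,
                 mol_ids = mol_ids, rigid_per_frame = rigid_per_frame),
            class = "fixture_spec")
}

#' Generate a synthetic data file + dump pair with ground truth
#'
#' Writes an atom style "full" data file and a text dump for the given
#' \code{\link{fixture_spec}} and returns the exact unwrapped coordinates,
#' bonds, masses and charges per frame as ground truth for tests.
#'
#' @param spec A \code{fixture_spec}.
#' @param dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return List with \code{data_path}, \code{dump_path} and \code{truth}
#'   (\code{atoms} data.frame, \code{bonds}, \code{box}, and
#'   \code{frames}: per-frame N x 3 unwrapped coordinate matrices in
#'   atom-id order).
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture"),
                             name = "system") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- spec$template
  n_tpl <- nrow(tpl$coords)
  n_atoms <- n_tpl * spec$copies
  box <- rbind(x = c(0, spec$box[1]), y = c(0, spec$box[2]),
               z = c(0, spec$box[3]))
  colnames(box) <- c("lo", "hi")

  # atom types keyed by distinct mass
  u_mass <- unique(tpl$masses)
  a_type <- match(tpl$masses, u_mass)

  set.seed(spec$seed)
  # grid placement of copies, jittered, centred in the box
  ngrid <- ceiling(spec$copies^(1 / 3))
  cell <- spec$box / ngrid
  idx <- (seq_len(spec$copies) - 1)
  centers <- cbind((idx %% ngrid + 0.5) * cell[1],
                   ((idx %/% ngrid) %% ngrid + 0.5) * cell[2],
                   (idx %/% (ngrid^2) + 0.5) * cell[3])

  atoms <- data.frame(
    id = seq_len(n_atoms),
    mol = rep(spec$mol_ids, each = n_tpl),
    type = rep(a_type, spec$copies),
    q = rep(tpl$charges, spec$copies)
  )
  bonds <- do.call(rbind, lapply(seq_len(spec$copies) - 1L, function(c0) {
    tpl$bonds + c0 * n_tpl
  }))

  frame_coords <- vector("list", spec$frames)
  base <- lapply(seq_len(spec$copies), function(c1) {
    Rm <- random_rotation(spec$seed * 1000L + c1)
    rigid_motion(tpl$coords, Rm, centers[c1, ])
  })
  for (f in seq_len(spec$frames)) {
    if (f == 1 || !spec$rigid_per_frame) {
      cur <- base
    } else {
      cur <- lapply(seq_len(spec$copies), function(c1) {
        Rm <- random_rotation(spec$seed * 100000L + f * 97L + c1)
        set.seed(spec$seed * 100000L + f * 131L + c1)
        tr <- stats::runif(3, 0.25, 0.75) * spec$box
        ctr <- colMeans(base[[c1]])
        rigid_motion(sweep(base[[c1]], 2, ctr), Rm, tr)
      })
    }
    frame_coords[[f]] <- do.call(rbind, cur)
  }

  data_path <- file.path(dir, paste0(name, ".data"))
  dump_path <- file.path(dir, paste0(name, ".lammpstrj"))
  write_data_file(data_path, atoms, frame_coords[[1]], tpl$masses[a_type],
                  u_mass, bonds, box)
  write_dump_file(dump_path, atoms, frame_coords, box, wrap = spec$wrap)
  list(data_path = data_path, dump_path = dump_path,
       truth = list(atoms = atoms, bonds = bonds, box = box,
                    masses_by_type = u_mass,
                    frames = frame_coords))
}

.fmt <- function(x) sprintf("%.17g", x)

# write an atom style "full" data file
write_data_file <- function(path, atoms, coords, atom_mass, u_mass, bonds,
                            box) {
  lines <- c(
    "synthetic fixture",
    "",
    paste(nrow(atoms), "atoms"),
    paste(nrow(bonds), "bonds"),
    paste(length(u_mass), "atom types"),
    "1 bond types",
    "",
    paste(.fmt(box["x", 1]), .fmt(box["x", 2]), "xlo xhi"),
    paste(.fmt(box["y", 1]), .fmt(box["y", 2]), "ylo yhi"),
    paste(.fmt(box["z", 1]), .fmt(box["z", 2]), "zlo zhi"),
    "",
    "Masses",
    "",
    paste(seq_along(u_mass), .fmt(u_mass)),
    "",
    "Atoms # full",
    "",
    paste(atoms$id, atoms$mol, atoms$type, .fmt(atoms$q),
          .fmt(coords[, 1]), .fmt(coords[, 2]), .fmt(coords[, 3])),
    "",
    "Bonds",
    "",
    paste(seq_len(nrow(bonds)), 1L, bonds[, 1], bonds[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}

# write a text dump; wrap = TRUE folds coordinates into the box
write_dump_file <- function(path, atoms, frame_coords, box, wrap = FALSE,
                            timesteps = NULL) {
  if (is.null(timesteps)) timesteps <- seq_along(frame_coords) - 1L
  L <- box[, "hi"] - box[, "lo"]
  cols <- if (wrap) "x y z" else "xu yu zu"
  out <- character(0)
  for (f in seq_along(frame_coords)) {
    X <- frame_coords[[f]]
    if (wrap) {
      X <- sweep(sweep(X, 2, box[, "lo"]) %% L, 2, -box[, "lo"])
    }
    out <- c(out,
      "ITEM: TIMESTEP", as.character(timesteps[f]),
      "ITEM: NUMBER OF ATOMS", as.character(nrow(atoms)),
      "ITEM: BOX BOUNDS pp pp pp",
      paste(.fmt(box["x", 1]), .fmt(box["x", 2])),
      paste(.fmt(box["y", 1]), .fmt(box["y", 2])),
      paste(.fmt(box["z", 1]), .fmt(box["z", 2])),
      paste("ITEM: ATOMS id mol type q", cols),
      paste(atoms$id, atoms$mol, atoms$type, .fmt(atoms$q),
            .fmt(X[, 1]), .fmt(X[, 2]), .fmt(X[, 3]))
    )
  }
  writeLines(out, path)
  invisible(path)
}
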