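# Set 2: geometric shape and size descriptors.

DEBYE_PER_E_ANGSTROM <- 4.8032

geometric_names <- function() {
  c("dipole_debye",
    "I1", "I2", "I3", "I1/I2", "I1/I3", "I2/I3", "inertialShapeFactor",
    "Rg", "asphericity", "acylindricity", "kappa2",
    "grav1", "grav2", "molvolume",
    paste0("S", 1:6), "PBF",
    "span", "diameter3D_geo", "Ree", "Lcontour", "lk",
    paste0("phi", 1:10))
}

# mass-weighted centre
.com <- function(X, m) colSums(X * m) / sum(m)

#' Dipole moment magnitude
#'
#' \eqn{\mu = \lVert \sum_i q_i (r_i - r_{com}) \rVert} about the
#' mass-weighted centre, converted from e Angstrom to Debye (factor
#' 4.8032).  Using the centre of mass as origin gives charged species a
#' defined, if origin-dependent, value.
#'
#' @param X N x 3 coordinates (Angstrom).
#' @param q Partial charges (e).
#' @param m Atomic masses (g/mol).
#' @return Dipole moment in Debye.
#' @export
dipole_moment <- function(X, q, m) {
  Xc <- sweep(as.matrix(X), 2, .com(X, m))
  sqrt(sum(colSums(Xc * q)^2)) * DEBYE_PER_E_ANGSTROM
}

# principal moments of inertia (amu Angstrom^2, ascending) and the
# mass-weighted gyration-tensor shape set
.inertia_gyration <- function(X, m) {
  Xc <- sweep(as.matrix(X), 2, .com(X, m))
  r2 <- rowSums(Xc^2)
  It <- diag(sum(m * r2), 3) - t(Xc * m) %*% Xc
  I123 <- sort(pmax(eigen(It, symmetric = TRUE)$values, 0))
  Sg <- t(Xc * m) %*% Xc / sum(m)
  lam <- sort(pmax(eigen(Sg, symmetric = TRUE)$values, 0))  # la <= lb <= lc
  Rg2 <- sum(lam)
  asph <- lam[3] - (lam[1] + lam[2]) / 2
  acyl <- lam[2] - lam[1]
  kappa2 <- if (Rg2 > 0) (asph^2 + 0.75 * acyl^2) / Rg2^2 else 0
  rat <- function(a, b) if (b > 0) a / b else 0
  list(I = I123,
       ratios = c(rat(I123[1], I123[2]), rat(I123[1], I123[3]),
                  rat(I123[2], I123[3])),
       isf = if (I123[1] * I123[3] > 0) I123[2] / (I123[1] * I123[3]) else 0,
       Rg = sqrt(Rg2), asphericity = asph, acylindricity = acyl,
       kappa2 = kappa2, gyration_axes = eigen(Sg, symmetric = TRUE)$vectors)
}

# gravitation indices: all-pairs and bonded-pairs sums of m_i m_j / r_ij^2
.gravitation <- function(D, m, bonds_idx) {
  n <- length(m)
  g1 <- 0
  if (n >= 2) {
    iu <- which(upper.tri(D), arr.ind = TRUE)
    r <- D[iu]
    ok <- r > 0
    g1 <- sum(m[iu[ok, 1]] * m[iu[ok, 2]] / r[ok]^2)
  }
  g2 <- 0
  if (nrow(bonds_idx)) {
    r <- D[bonds_idx]
    ok <- r > 0
    g2 <- sum(m[bonds_idx[ok, 1]] * m[bonds_idx[ok, 2]] / r[ok]^2)
  }
  c(g1, g2)
}

#' Van der Waals molecular volume
#'
#' Volume of the union of van der Waals spheres, counted on a cubic grid:
#' a voxel contributes if its centre lies inside any sphere.
#'
#' @param X N x 3 coordinates (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom).
#' @param spacing Grid spacing in Angstrom (default 0.2).
#' @return Volume in cubic Angstrom.
#' @export
mol_volume <- function(X, radii, spacing = 0.2) {
  X <- as.matrix(X)
  lo <- apply(X - radii, 2, min) - spacing
  hi <- apply(X + radii, 2, max) + spacing
  gx <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
  gy <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
  gz <- seq(lo[3] + spacing / 2, hi[3], by = spacing)
  inside <- array(FALSE, c(length(gx), length(gy), length(gz)))
  for (i in seq_len(nrow(X))) {
    dx2 <- (gx - X[i, 1])^2
    dy2 <- (gy - X[i, 2])^2
    dz2 <- (gz - X[i, 3])^2
    r2 <- radii[i]^2
    # restrict to the sphere's bounding sub-grid
    sx <- which(dx2 <= r2); sy <- which(dy2 <= r2); sz <- which(dz2 <= r2)
    if (!length(sx) || !length(sy) || !length(sz)) next
    sub <- outer(dx2[sx], dy2[sy], "+")
    for (k in seq_along(sz)) {
      inside[sx, sy, sz[k]] <- inside[sx, sy, sz[k]] | (sub + dz2[sz[k]] <= r2)
    }
  }
  sum(inside) * spacing^3
}

# union-of-disks area on a 2D grid; returns c(area, rect_fraction)
.disk_union_area <- function(U, V, radii, spacing = 0.1) {
  lo_u <- min(U - radii) - spacing; hi_u <- max(U + radii) + spacing
  lo_v <- min(V - radii) - spacing; hi_v <- max(V + radii) + spacing
  gu <- seq(lo_u + spacing / 2, hi_u, by = spacing)
  gv <- seq(lo_v + spacing / 2, hi_v, by = spacing)
  inside <- matrix(FALSE, length(gu), length(gv))
  for (i in seq_along(U)) {
    du2 <- (gu - U[i])^2; dv2 <- (gv - V[i])^2
    r2 <- radii[i]^2
    su <- which(du2 <= r2); sv <- which(dv2 <= r2)
    if (!length(su) || !length(sv)) next
    inside[su, sv] <- inside[su, sv] | (outer(du2[su], dv2[sv], "+") <= r2)
  }
  area <- sum(inside) * spacing^2
  rect <- (max(U + radii) - min(U - radii)) * (max(V + radii) - min(V - radii))
  c(area, area / rect)
}

#' Shadow indices
#'
#' Areas of the molecule's projection onto the three principal planes of
#' the mass-weighted gyration tensor (union of van der Waals disks on a
#' 0.1 Angstrom grid), plus the same areas normalised by the enclosing
#' axis-aligned rectangle of each projection.
#'
#' @param X N x 3 coordinates; \code{m} masses; \code{radii} van der Waals
#'   radii (Angstrom); \code{spacing} grid step.
#' @param m,radii,spacing See above.
#' @return Named numeric S1..S6.
#' @export
shadow_indices <- function(X, m, radii, spacing = 0.1) {
  ig <- .inertia_gyration(X, m)
  Xc <- sweep(as.matrix(X), 2, .com(X, m))
  P <- Xc %*% ig$gyration_axes  # principal frame
  s1 <- .disk_union_area(P[, 2], P[, 3], radii, spacing)  # onto yz
  s2 <- .disk_union_area(P[, 1], P[, 3], radii, spacing)  # onto xz
  s3 <- .disk_union_area(P[, 1], P[, 2], radii, spacing)  # onto xy
  stats::setNames(c(s1[1], s2[1], s3[1], s1[2], s2[2], s3[2]),
                  paste0("S", 1:6))
}

#' Plane of best fit score
#'
#' Mean absolute distance of the atoms from the best plane through the
#' centroid, minimised over plane orientations.  The search starts from
#' the principal directions of the centred coordinates plus a
#' deterministic spherical grid and refines the best candidates by local
#' optimisation, so degenerate (isotropic) geometries where the principal
#' directions are arbitrary are still scored correctly.  Zero for fewer
#' than three atoms.
#'
#' @param X N x 3 coordinates (Angstrom).
#' @return Mean deviation in Angstrom.
#' @export
pbf_score <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) return(0)
  Xc <- sweep(X, 2, colMeans(X))
  obj_n <- function(n) mean(abs(Xc %*% n))
  obj_ang <- function(a) {
    obj_n(c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1])))
  }
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$vectors
  k <- seq_len(512) - 1
  z <- 1 - (2 * k + 1) / 512
  ph <- k * pi * (3 - sqrt(5))
  grid <- rbind(t(ev), cbind(sqrt(1 - z^2) * cos(ph),
                             sqrt(1 - z^2) * sin(ph), z))
  vals <- apply(grid, 1, obj_n)
  best <- min(vals)
  ctrl <- list(reltol = 1e-12, maxit = 500)
  for (i in order(vals)[1:10]) {
    n0 <- grid[i, ]
    a0 <- c(acos(max(-1, min(1, n0[3]))), atan2(n0[2], n0[1]))
    o <- stats::optim(a0, obj_ang, control = ctrl)
    o <- stats::optim(o$par, obj_ang, control = ctrl)  # polish
    if (o$value < best) best <- o$value
  }
  best
}

# backbone path: one shortest path realising the topological diameter,
# ties broken by the lexicographically smallest atom-id sequence
.backbone_path <- function(snapshot) {
  n <- nrow(snapshot$d_top)
  if (n < 2) return(1L)
  dt <- snapshot$d_top
  diam <- max(dt)
  if (diam == 0) return(1L)
  g <- igraph::graph_from_adjacency_matrix(snapshot$adjacency,
                                           mode = "undirected")
  ends <- which(dt == diam, arr.ind = TRUE)
  ends <- ends[ends[, 1] < ends[, 2], , drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(ends))) {
    for (pair in list(ends[r, ], rev(ends[r, ]))) {
      ps <- igraph::all_shortest_paths(g, from = pair[1], to = pair[2])$res
      for (p in ps) {
        ids <- snapshot$atom_ids[as.integer(p)]
        seq_local <- as.integer(p)
        if (is.null(best) || .lex_less(ids, best_ids)) {
          best <- seq_local; best_ids <- ids
        }
      }
    }
  }
  best
}

.lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Chain extension and folding measures
#'
#' Size measures (span about the centre of mass, maximal interatomic
#' distance) and backbone measures along one shortest path realising the
#' topological diameter: end-to-end distance Ree, contour length, Kuhn
#' length \eqn{l_k = R_{ee}^2 / L_{contour}}, and folding profiles
#' \eqn{\phi_k}: the mean, over all windows of k consecutive backbone
#' bonds, of the through-space distance between the window ends divided by
#' the contour length of the window (1 for a fully extended window, < 1
#' when folded; 0 when the backbone is shorter than k bonds).
#'
#' @param snapshot Molecule snapshot.
#' @return Named numeric: span, diameter3D_geo, Ree, Lcontour, lk,
#'   phi1..phi10.
#' @export
chain_measures <- function(snapshot) {
  X <- snapshot$coords; D <- snapshot$dist; m <- snapshot$mass
  out <- stats::setNames(numeric(15),
                         c("span", "diameter3D_geo", "Ree", "Lcontour",
                           "lk", paste0("phi", 1:10)))
  Xc <- sweep(as.matrix(X), 2, .com(X, m))
  out["span"] <- sqrt(max(rowSums(Xc^2)))
  out["diameter3D_geo"] <- max(D)
  path <- .backbone_path(snapshot)
  mseg <- length(path) - 1
  if (mseg >= 1) {
    blen <- D[cbind(path[-length(path)], path[-1])]
    out["Ree"] <- D[path[1], path[length(path)]]
    out["Lcontour"] <- sum(blen)
    out["lk"] <- if (out["Lcontour"] > 0) out["Ree"]^2 / out["Lcontour"] else 0
    for (k in 1:10) {
      if (mseg < k) next
      starts <- seq_len(mseg - k + 1)
      ratios <- vapply(starts, function(i) {
        seg <- sum(blen[i:(i + k - 1)])
        if (seg > 0) D[path[i], path[i + k]] / seg else 0
      }, 0)
      out[paste0("phi", k)] <- mean(ratios)
    }
  }
  out
}

#' Set 2: geometric descriptors
#'
#' Dipole moment, principal moments of inertia and their ratios, gyration
#' shape set, gravitation indices, van der Waals volume, shadow indices,
#' plane-of-best-fit score, and chain extension/folding measures — 37
#' descriptors in fixed order.
#'
#' @param snapshot Molecule snapshot.
#' @param volume_spacing Grid step for the volume integration (Angstrom).
#' @param shadow_spacing Grid step for the shadow projections (Angstrom).
#' @return Named numeric vector of length 37.
#' @export
geometric_block <- function(snapshot, volume_spacing = 0.2,
                            shadow_spacing = 0.1) {
  X <- snapshot$coords; m <- snapshot$mass
  ig <- .inertia_gyration(X, m)
  vals <- c(
    dipole_moment(X, snapshot$q, m),
    ig$I, ig$ratios, ig$isf,
    ig$Rg, ig$asphericity, ig$acylindricity, ig$kappa2,
    .gravitation(snapshot$dist, m, snapshot$bonds_idx),
    mol_volume(X, snapshot$vdw_radius, volume_spacing),
    shadow_indices(X, m, snapshot$vdw_radius, shadow_spacing),
    pbf_score(X),
    chain_measures(snapshot)
  )
  stats::setNames(unname(vals), geometric_names())
}
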