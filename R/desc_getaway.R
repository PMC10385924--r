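# Set 3: GETAWAY descriptors (GEometry, Topology and Atom-Weights
# AssemblY) built on the molecular influence matrix of the centred
# coordinates.

.getaway_schemes <- c("u", "m", "c", "v", "e", "p", "i", "a")

getaway_names <- function() {
  per_scheme <- function(w) {
    c(paste0("H", 0:8, w), paste0("HT", w),
      paste0("HATS", 0:8, w), paste0("HATST", w),
      paste0("R", 1:8, w), paste0("RT", w),
      paste0("Rmax", 1:8, w), paste0("RmaxT", w))
  }
  c("ITH", "ISH", "HIC", "HGM", "RARS", "RCON", "REIG",
    unlist(lapply(.getaway_schemes, per_scheme)))
}

#' Molecular influence (leverage) matrix
#'
#' \eqn{H = M (M^T M)^{+} M^T} of the centred coordinate matrix M, using
#' the Moore-Penrose pseudo-inverse so planar, linear and single-atom
#' geometries are handled; H is the orthogonal projector onto the column
#' space of M, its diagonal elements (leverages) measure each atom's
#' influence on the molecular geometry and its trace equals the rank of M
#' (3 for a generic 3D molecule).
#'
#' @param centered N x 3 centred coordinates.
#' @return List with \code{H} (N x N) and \code{leverages} (diagonal).
#' @export
influence_matrix <- function(centered) {
  M <- as.matrix(centered)
  n <- nrow(M)
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d, 0) * .Machine$double.eps
  keep <- sv$d > tol
  H <- if (any(keep)) {
    U <- sv$u[, keep, drop = FALSE]
    U %*% t(U)
  } else {
    matrix(0, n, n)
  }
  list(H = H, leverages = diag(H))
}

# group sizes of near-equal values (gap tolerance)
.equivalence_sizes <- function(x, tol = 1e-6) {
  xs <- sort(x)
  brk <- c(0, which(diff(xs) > tol), length(xs))
  diff(brk)
}

#' Set 3: GETAWAY descriptors
#'
#' Seven scalar descriptors of the leverage distribution (total and
#' standardised information content ITH/ISH, mean information content HIC,
#' leverage geometric mean HGM, R-matrix average row sum RARS, R
#' connectivity RCON and R-matrix leading eigenvalue REIG) plus, for each
#' of eight atomic weighting schemes (unit, mass, charge, van der Waals
#' volume, electronegativity, polarizability, ionization potential,
#' electron affinity; non-charge weights carbon-scaled), lag-indexed
#' autocorrelation vectors over topological distance k: H_k and HATS_k
#' (k = 0..8) from the influence matrix, and R_k / Rmax_k (k = 1..8) from
#' the influence/geometry matrix \eqn{R_{ij} = \sqrt{h_i h_j}/r_{ij}},
#' each with its total — 311 descriptors.
#'
#' @param snapshot Molecule snapshot.
#' @return Named numeric vector of length 311, fixed order.
#' @export
getaway_block <- function(snapshot) {
  n <- nrow(snapshot$coords)
  im <- influence_matrix(snapshot$centered)
  H <- im$H; h <- im$leverages
  D <- snapshot$dist
  dt <- snapshot$d_top

  # R matrix (zero diagonal; coincident atoms contribute 0)
  Rm <- matrix(0, n, n)
  if (n >= 2) {
    off <- which(upper.tri(D) & D > 0, arr.ind = TRUE)
    v <- sqrt(h[off[, 1]] * h[off[, 2]]) / D[cbind(off[, 1], off[, 2])]
    Rm[off] <- v
    Rm[off[, c(2, 1), drop = FALSE]] <- v
  }

  out <- stats::setNames(numeric(length(getaway_names())), getaway_names())

  if (n >= 2) {
    Ng <- .equivalence_sizes(h)
    out["ITH"] <- n * log2(n) - sum(Ng * log2(Ng))
    out["ISH"] <- out["ITH"] / (n * log2(n))
  }
  sH <- sum(h)
  if (sH > 0) {
    p <- h[h > 0] / sH
    out["HIC"] <- -sum(p * log2(p))
  }
  if (any(h > 0)) {
    out["HGM"] <- 100 * exp(sum(log(h[h > 0])) / n)
  }
  RS <- rowSums(Rm)
  out["RARS"] <- sum(RS) / n
  if (nrow(snapshot$bonds_idx)) {
    out["RCON"] <- sum(sqrt(RS[snapshot$bonds_idx[, 1]] *
                            RS[snapshot$bonds_idx[, 2]]))
  }
  if (n >= 2) out["REIG"] <- max(eigen(Rm, symmetric = TRUE,
                                       only.values = TRUE)$values)

  iu <- which(upper.tri(D), arr.ind = TRUE)
  lag <- if (nrow(iu)) dt[iu] else integer(0)
  Hij <- if (nrow(iu)) H[iu] else numeric(0)
  Rij <- if (nrow(iu)) Rm[iu] else numeric(0)

  for (w in .getaway_schemes) {
    wv <- snapshot$weights[[w]]
    wp <- if (nrow(iu)) wv[iu[, 1]] * wv[iu[, 2]] else numeric(0)
    hw <- h * wv
    hwp <- if (nrow(iu)) hw[iu[, 1]] * hw[iu[, 2]] else numeric(0)
    Hk <- numeric(9); HATSk <- numeric(9)
    Hk[1] <- sum(h * wv^2)
    HATSk[1] <- sum(hw^2)
    Rk <- numeric(8); Rmaxk <- numeric(8)
    for (k in 1:8) {
      at <- lag == k
      sel <- at & Hij > 0
      Hk[k + 1] <- sum(Hij[sel] * wp[sel])
      HATSk[k + 1] <- sum(hwp[at])
      terms <- Rij[at] * wp[at]
      Rk[k] <- sum(terms)
      Rmaxk[k] <- if (length(terms)) max(terms) else 0
    }
    out[paste0("H", 0:8, w)] <- Hk
    out[paste0("HT", w)] <- sum(Hk)
    out[paste0("HATS", 0:8, w)] <- HATSk
    out[paste0("HATST", w)] <- sum(HATSk)
    out[paste0("R", 1:8, w)] <- Rk
    out[paste0("RT", w)] <- sum(Rk)
    out[paste0("Rmax", 1:8, w)] <- Rmaxk
    out[paste0("RmaxT", w)] <- sum(Rmaxk)
  }
  out
}
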