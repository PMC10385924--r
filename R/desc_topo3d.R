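# Set 1: 3D topology and 3D connectivity descriptors.
#
# All indices are evaluated on the geometric (Euclidean) distance matrix of
# the unwrapped conformation rather than on integer graph distances, so
# they respond to conformational change frame by frame.  The same eleven
# indices are repeated on the hydrogen-suppressed graph (suffix _hs): all
# explicit H atoms and their bonds are dropped and the indices recomputed
# on the heavy-atom subgraph, the usual convention for topological indices.

.topo3d_names_base <- c("W3D", "H3D", "AGD", "J3D", "radius3D",
                        "diameter3D", "meanEcc3D", "petitjean3D",
                        "chi0_3D", "chi1_3D", "chi2_3D")

topo3d_names <- function() {
  c(.topo3d_names_base, paste0(.topo3d_names_base, "_hs"))
}

# core 11 indices for one (sub)molecule
.topo3d_core <- function(D, adj, bonds_idx) {
  out <- stats::setNames(numeric(length(.topo3d_names_base)),
                         .topo3d_names_base)
  n <- nrow(D)
  if (is.null(n) || n < 2) return(out)
  iu <- upper.tri(D)
  W3D <- sum(D[iu])
  out["W3D"] <- W3D
  pos <- D[iu] > 0
  out["H3D"] <- sum(1 / D[iu][pos])
  out["AGD"] <- W3D / (n * (n - 1) / 2)
  ecc <- apply(D, 1, max)
  out["radius3D"] <- min(ecc)
  out["diameter3D"] <- max(ecc)
  out["meanEcc3D"] <- mean(ecc)
  out["petitjean3D"] <- if (min(ecc) > 0) {
    (max(ecc) - min(ecc)) / min(ecc)
  } else 0

  B <- nrow(bonds_idx)
  if (B > 0) {
    S <- rowSums(D)
    cyc <- B - n + 1
    si <- S[bonds_idx[, 1]]; sj <- S[bonds_idx[, 2]]
    ok <- si > 0 & sj > 0
    out["J3D"] <- (B / (cyc + 1)) * sum(1 / sqrt(si[ok] * sj[ok]))

    deg <- rowSums(adj)
    blen <- D[bonds_idx]
    mbl <- mean(blen)
    out["chi0_3D"] <- sum(1 / sqrt(deg[deg > 0])) * mbl
    out["chi1_3D"] <- sum(1 / sqrt(deg[bonds_idx[, 1]] *
                                   deg[bonds_idx[, 2]])) * mbl
    # 2-paths i-j-k, each unordered triple counted once
    chi2 <- 0
    for (j in seq_len(n)) {
      nb <- which(adj[j, ] == 1L)
      if (length(nb) >= 2) {
        prs <- utils::combn(nb, 2)
        chi2 <- chi2 + sum(1 / sqrt(deg[prs[1, ]] * deg[j] * deg[prs[2, ]]))
      }
    }
    out["chi2_3D"] <- chi2 * mbl
  }
  out
}

#' Set 1: 3D topology and connectivity descriptors
#'
#' Computes 22 descriptors from the geometric distance matrix and the bond
#' graph of one molecule snapshot: the 3D Wiener index (sum of all
#' interatomic distances), 3D Harary index (sum of reciprocal distances),
#' average geometric distance, a Balaban-type 3D index over distance-matrix
#' row sums, geometric eccentricity statistics (radius, diameter, mean,
#' Petitjean shape index), and Randic-type connectivity indices of order
#' 0-2 scaled by the mean bond length; all eleven are then repeated on the
#' hydrogen-suppressed graph (\code{_hs} suffix).
#'
#' @param snapshot A molecule snapshot (internal structure produced by the
#'   engine; see \code{\link{compute_descriptors}} for the user-facing
#'   entry point).
#' @return Named numeric vector of length 22, fixed order.
#' @export
topo3d <- function(snapshot) {
  full <- .topo3d_core(snapshot$dist, snapshot$adjacency,
                       snapshot$bonds_idx)
  keep <- snapshot$element != "H"
  if (all(keep)) {
    hs <- full
  } else {
    bi <- snapshot$bonds_idx
    bkeep <- keep[bi[, 1]] & keep[bi[, 2]]
    remap <- cumsum(keep)
    bi2 <- cbind(remap[bi[bkeep, 1]], remap[bi[bkeep, 2]])
    hs <- .topo3d_core(snapshot$dist[keep, keep, drop = FALSE],
                       snapshot$adjacency[keep, keep, drop = FALSE],
                       bi2)
  }
  stats::setNames(c(full, hs), topo3d_names())
}
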