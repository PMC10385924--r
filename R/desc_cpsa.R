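# Set 4: charged partial surface area descriptors over a
# solvent-accessible surface area engine.

cpsa_names <- function() {
  c(paste0("PPSA", 1:3), paste0("PNSA", 1:3), paste0("DPSA", 1:3),
    paste0("FPSA", 1:3), paste0("FNSA", 1:3),
    paste0("WPSA", 1:3), paste0("WNSA", 1:3),
    "RPCG", "RNCG", "RPCS", "RNCS",
    "TASA", "TPSA", "RASA", "RPSA", "SASA_total")
}

# deterministic golden-spiral point set on the unit sphere
.sphere_points <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  phi <- k * pi * (3 - sqrt(5))
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral test points are placed on each atom's
#' expanded sphere of radius \eqn{r_i + probe}; a point is accessible if
#' it lies strictly outside every other atom's expanded sphere (a point
#' exactly on another sphere's boundary counts as accessible).  The
#' per-atom area is the accessible fraction of \eqn{4\pi(r_i+probe)^2}.
#'
#' @param X N x 3 coordinates (Angstrom).
#' @param radii Van der Waals radii (Angstrom).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960; at least 64).
#' @return List with \code{per_atom} areas, \code{total} and
#'   \code{n_points}.
#' @export
sasa <- function(X, radii, probe = 1.4, n_points = 960) {
  stopifnot(probe >= 0, n_points >= 64)
  X <- as.matrix(X)
  n <- nrow(X)
  re <- radii + probe
  pts <- .sphere_points(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    P <- sweep(pts * re[i], 2, -X[i, ])  # points on atom i's sphere
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      if (sum((X[j, ] - X[i, ])^2) >= (re[i] + re[j])^2) next
      d2 <- (P[, 1] - X[j, 1])^2 + (P[, 2] - X[j, 2])^2 +
            (P[, 3] - X[j, 3])^2
      acc <- acc & (d2 >= re[j]^2 - 1e-9)
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * re[i]^2 * mean(acc)
  }
  list(per_atom = per_atom, total = sum(per_atom), n_points = n_points)
}

#' Set 4: charged partial surface area descriptors
#'
#' The 30 CPSA descriptors combine partial charges with per-atom
#' solvent-accessible surface areas: partial positive/negative surface
#' areas PPSA1-3 / PNSA1-3 (plain, total-charge-weighted and
#' atom-charge-weighted sums), their differences DPSA1-3, fractions
#' FPSA/FNSA (divided by the total area), surface-weighted WPSA/WNSA
#' (times total area / 1000), relative charges and charged surfaces
#' RPCG/RNCG/RPCS/RNCS, and the polar/apolar split TPSA/TASA/RPSA/RASA
#' with atoms of \eqn{|q| \ge} \code{polar_threshold} counted as polar.
#'
#' @param sasa_result Result of \code{\link{sasa}}.
#' @param q Partial charges (e), aligned with the atoms.
#' @param polar_threshold Absolute charge above which an atom counts as
#'   polar (default 0.2 e).
#' @return Named numeric vector of length 30, fixed order.
#' @export
cpsa <- function(sasa_result, q, polar_threshold = 0.2) {
  SA <- sasa_result$per_atom
  TSA <- sasa_result$total
  pos <- q > 0; neg <- q < 0
  Qp <- sum(q[pos]); Qn <- sum(q[neg])
  PPSA <- c(sum(SA[pos]), Qp * sum(SA[pos]), sum(q[pos] * SA[pos]))
  PNSA <- c(sum(SA[neg]), Qn * sum(SA[neg]), sum(q[neg] * SA[neg]))
  DPSA <- PPSA - PNSA
  FPSA <- if (TSA > 0) PPSA / TSA else c(0, 0, 0)
  FNSA <- if (TSA > 0) PNSA / TSA else c(0, 0, 0)
  WPSA <- PPSA * TSA / 1000
  WNSA <- PNSA * TSA / 1000
  RPCG <- if (any(pos)) max(q[pos]) / Qp else 0
  RNCG <- if (any(neg)) abs(min(q[neg])) / abs(Qn) else 0
  RPCS <- if (any(pos)) SA[pos][which.max(q[pos])] * RPCG else 0
  RNCS <- if (any(neg)) SA[neg][which.min(q[neg])] * RNCG else 0
  polar <- abs(q) >= polar_threshold
  TPSA <- sum(SA[polar])
  TASA <- TSA - TPSA
  RPSA <- if (TSA > 0) TPSA / TSA else 0
  RASA <- if (TSA > 0) TASA / TSA else 0
  stats::setNames(
    c(PPSA, PNSA, DPSA, FPSA, FNSA, WPSA, WNSA,
      RPCG, RNCG, RPCS, RNCS, TASA, TPSA, RASA, RPSA, TSA),
    cpsa_names())
}

#' @rdname cpsa
#' @param snapshot Molecule snapshot.
#' @param probe,n_points Passed to \code{\link{sasa}}.
#' @export
cpsa_block <- function(snapshot, probe = 1.4, n_points = 960,
                       polar_threshold = 0.2) {
  sr <- sasa(snapshot$coords, snapshot$vdw_radius, probe, n_points)
  cpsa(sr, snapshot$q, polar_threshold)
}
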