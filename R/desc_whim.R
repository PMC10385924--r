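# Set 5: WHIM descriptors — statistics of weighted-covariance
# principal-axis projections of the molecular geometry.

.whim_schemes <- c("u", "m", "c", "v", "e", "p", "i")

whim_names <- function() {
  per <- c("L1", "L2", "L3", "Th1", "Th2", "G1", "G2", "G3",
           "E1", "E2", "E3", "T", "A", "V", "K", "G")
  unlist(lapply(.whim_schemes, function(w) paste0(per, w)))
}

# symmetry tolerances for the gamma (symmetry) indices
.whim_pair_tol <- 0.5   # counterpart window on the score axis (Angstrom)
.whim_self_tol <- 0.25  # |t| below which an atom mirrors itself

# one weighting scheme: returns the 16 WHIM values
.whim_one <- function(X, w, elements) {
  n <- nrow(X)
  sw <- sum(w)
  xbar <- colSums(X * w) / sw
  Xc <- sweep(as.matrix(X), 2, xbar)
  S <- t(Xc * w) %*% Xc / sw
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)  # descending
  V <- ev$vectors
  # fix eigenvector signs: largest-magnitude component positive
  for (m in 1:3) {
    j <- which.max(abs(V[, m]))
    if (V[j, m] < 0) V[, m] <- -V[, m]
  }
  Tsum <- sum(lam)
  scores <- Xc %*% V
  th <- if (Tsum > 0) lam / Tsum else c(0, 0, 0)
  gam <- numeric(3); e <- numeric(3)
  for (m in 1:3) {
    t_m <- scores[, m]
    sym <- vapply(seq_len(n), function(i) {
      if (abs(t_m[i]) < .whim_self_tol) return(TRUE)
      any(elements == elements[i] &
            seq_len(n) != i &
            abs(t_m + t_m[i]) <= .whim_pair_tol)
    }, TRUE)
    gam[m] <- mean(sym)
    s4 <- sum(t_m^4)
    e[m] <- if (lam[m] > 0 && s4 > 0) lam[m]^2 * n / s4 else 0
  }
  A <- lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3]
  Vtot <- Tsum + A + lam[1] * lam[2] * lam[3]
  K <- if (Tsum > 0) sum(abs(lam / Tsum - 1 / 3)) / (4 / 3) else 0
  G <- (gam[1] * gam[2] * gam[3])^(1 / 3)
  c(lam, th[1], th[2], gam, e, Tsum, A, Vtot, K, G)
}

#' Set 5: WHIM descriptors
#'
#' For each of seven atomic weighting schemes (unit, mass, absolute
#' charge, van der Waals volume, electronegativity, polarizability,
#' ionization potential; non-charge weights carbon-scaled) the weighted
#' covariance matrix of the atomic coordinates is diagonalised and 11
#' directional plus 5 global statistics are reported: eigenvalues L1-L3
#' (size along each principal axis), proportions Th1-Th2 (shape),
#' symmetries G1-G3 (fraction of atoms with a mirror counterpart across
#' each principal plane), inverse kurtosis-type densities E1-E3, and the
#' totals T, A, V, the acentric factor K and the global symmetry G —
#' 112 descriptors.  A molecule whose charges are all zero falls back to
#' unit weights for the charge scheme; the returned vector then carries
#' the attribute \code{charge_fallback = TRUE}.
#'
#' @param snapshot Molecule snapshot.
#' @return Named numeric vector of length 112, fixed order.
#' @export
whim_block <- function(snapshot) {
  X <- snapshot$coords
  out <- stats::setNames(numeric(length(whim_names())), whim_names())
  fallback <- FALSE
  for (w in .whim_schemes) {
    wv <- if (w == "c") abs(snapshot$q) else snapshot$weights[[w]]
    if (sum(wv) == 0) {
      if (w == "c") {
        wv <- rep(1, nrow(X))
        fallback <- TRUE
      } else {
        stop("DegenerateWeights: scheme '", w, "' has zero total weight",
             call. = FALSE)
      }
    }
    vals <- .whim_one(X, wv, snapshot$element)
    out[paste0(c("L1", "L2", "L3", "Th1", "Th2", "G1", "G2", "G3",
                 "E1", "E2", "E3", "T", "A", "V", "K", "G"), w)] <- vals
  }
  if (fallback) attr(out, "charge_fallback") <- TRUE
  out
}
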