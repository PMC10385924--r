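# Set 6: RDF, 3D-MoRSE and 3D spatial autocorrelation descriptors.
#
# Grids: RDF sampled at 30 radii r_k = k/2 Angstrom (k = 1..30) with
# Gaussian smoothing beta = 100 A^-2; MoRSE at scattering values
# s = 0..29 A^-1; autocorrelations on 1-Angstrom distance bins [k, k+1)
# for k = 0..29.  RDF and MoRSE use 8 pair-weight schemes (unit + 7
# carbon-scaled properties, charge raw); the autocorrelations use the 7
# named physicochemical properties.

.field_schemes8 <- c("u", "m", "c", "v", "e", "p", "i", "a")
.field_props7 <- c("c", "m", "v", "e", "p", "i", "a")
RDF_BETA <- 100

rdf_names <- function() {
  unlist(lapply(.field_schemes8,
                function(w) sprintf("RDF%03d%s", (1:30) * 5, w)))
}
morse_names <- function() {
  unlist(lapply(.field_schemes8, function(w) sprintf("Mor%02d%s", 1:30, w)))
}
autocorr_names <- function(prefix) {
  unlist(lapply(.field_props7, function(p) sprintf("%s%d%s", prefix, 0:29, p)))
}
field3d_names <- function() {
  c(rdf_names(), morse_names(),
    autocorr_names("ATS"), autocorr_names("MATS"), autocorr_names("GATS"))
}

# upper-triangle pair indices and distances
.pairs <- function(D) {
  iu <- which(upper.tri(D), arr.ind = TRUE)
  list(i = iu[, 1], j = iu[, 2], r = D[iu])
}

#' Set 6: radial distribution function descriptors
#'
#' \eqn{R_w(r_k) = \sum_{i<j} w_i w_j e^{-\beta (r_k - r_{ij})^2}} with
#' \eqn{\beta = 100} per square Angstrom, sampled at
#' \eqn{r_k = 0.5, 1.0, \dots, 15} Angstrom, for the 8 weighting schemes.
#'
#' @param snapshot Molecule snapshot.
#' @return Named numeric vector of length 240.
#' @export
rdf_block <- function(snapshot) {
  out <- stats::setNames(numeric(240), rdf_names())
  n <- nrow(snapshot$coords)
  if (n < 2) return(out)
  p <- .pairs(snapshot$dist)
  G <- vapply((1:30) / 2, function(rk) exp(-RDF_BETA * (rk - p$r)^2),
              numeric(length(p$r)))
  G <- matrix(G, nrow = length(p$r))
  for (w in .field_schemes8) {
    wv <- snapshot$weights[[w]]
    wp <- wv[p$i] * wv[p$j]
    out[sprintf("RDF%03d%s", (1:30) * 5, w)] <- colSums(G * wp)
  }
  out
}

#' Set 6: 3D-MoRSE descriptors
#'
#' Scattering-function transform of the geometry,
#' \eqn{I_w(s) = \sum_{i<j} w_i w_j \sin(s r_{ij})/(s r_{ij})} with
#' \eqn{\mathrm{sinc}(0) = 1}, at \eqn{s = 0, 1, \dots, 29} per Angstrom,
#' for the 8 weighting schemes.
#'
#' @param snapshot Molecule snapshot.
#' @return Named numeric vector of length 240.
#' @export
morse_block <- function(snapshot) {
  out <- stats::setNames(numeric(240), morse_names())
  n <- nrow(snapshot$coords)
  if (n < 2) return(out)
  p <- .pairs(snapshot$dist)
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  S <- vapply(0:29, function(s) sinc(s * p$r), numeric(length(p$r)))
  S <- matrix(S, nrow = length(p$r))
  for (w in .field_schemes8) {
    wv <- snapshot$weights[[w]]
    wp <- wv[p$i] * wv[p$j]
    out[sprintf("Mor%02d%s", 1:30, w)] <- colSums(S * wp)
  }
  out
}

#' Set 6: 3D spatial autocorrelation descriptors
#'
#' Moreau-Broto (ATS), Moran (MATS) and Geary (GATS) autocorrelations of
#' the seven atomic properties over geometric distance bins
#' \eqn{[k, k+1)} Angstrom, \eqn{k = 0..29}.  With pair set \eqn{P_k} of
#' size \eqn{\Delta_k}, property mean \eqn{\bar w} and total sum of
#' squares \eqn{s^2}: \eqn{ATS_k = \sum_{P_k} w_i w_j};
#' \eqn{MATS_k = [\Delta_k^{-1} \sum (w_i-\bar w)(w_j-\bar w)] /
#' [N^{-1} s^2]}; \eqn{GATS_k = [(2\Delta_k)^{-1} \sum (w_i-w_j)^2] /
#' [(N-1)^{-1} s^2]}.  Empty bins and property vectors with zero variance
#' yield exactly 0 for MATS/GATS.
#'
#' @param snapshot Molecule snapshot.
#' @return Named numeric vector of length 630 (ATS, MATS, GATS).
#' @export
autocorr_block <- function(snapshot) {
  nm <- c(autocorr_names("ATS"), autocorr_names("MATS"),
          autocorr_names("GATS"))
  out <- stats::setNames(numeric(length(nm)), nm)
  n <- nrow(snapshot$coords)
  if (n < 2) return(out)
  p <- .pairs(snapshot$dist)
  bin <- floor(p$r)  # bin k holds r in [k, k+1)
  for (pr in .field_props7) {
    wv <- snapshot$weights[[pr]]
    wbar <- mean(wv)
    s2 <- sum((wv - wbar)^2)
    ats <- numeric(30); mats <- numeric(30); gats <- numeric(30)
    for (k in 0:29) {
      at <- bin == k
      dk <- sum(at)
      if (dk == 0) next
      wi <- wv[p$i[at]]; wj <- wv[p$j[at]]
      ats[k + 1] <- sum(wi * wj)
      if (s2 > 0) {
        mats[k + 1] <- (sum((wi - wbar) * (wj - wbar)) / dk) / (s2 / n)
        gats[k + 1] <- (sum((wi - wj)^2) / (2 * dk)) / (s2 / (n - 1))
      }
    }
    out[sprintf("ATS%d%s", 0:29, pr)] <- ats
    out[sprintf("MATS%d%s", 0:29, pr)] <- mats
    out[sprintf("GATS%d%s", 0:29, pr)] <- gats
  }
  out
}

#' Set 6: all field descriptors
#'
#' Concatenation of \code{\link{rdf_block}}, \code{\link{morse_block}}
#' and \code{\link{autocorr_block}} — 1110 descriptors.
#'
#' @param snapshot Molecule snapshot.
#' @return Named numeric vector of length 1110.
#' @export
field3d_block <- function(snapshot) {
  c(rdf_block(snapshot), morse_block(snapshot), autocorr_block(snapshot))
}
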