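#' Atomic property table
#'
#' Fixed table of atomic physicochemical properties used to weight
#' descriptors: standard atomic mass (g/mol), Bondi van der Waals radius
#' (Angstrom), van der Waals volume (Angstrom^3, computed as (4/3)*pi*r^3),
#' Pauling electronegativity, static dipole polarizability (Angstrom^3),
#' first ionization potential (eV), electron affinity (eV) and covalent
#' radius (Angstrom).  Besides the ten elements common in organic force
#' fields, the table carries united-atom carbon pseudo-elements (CH, CH2,
#' CH3, CH4) that inherit carbon's radius, volume and electronic properties
#' but keep their own mass, so united-atom force fields such as TraPPE-UA
#' are handled transparently.
#'
#' All property weights consumed by the descriptor families except charge
#' are scaled relative to the carbon entry (\code{w = p / p_C}); partial
#' charges are used raw, in units of elementary charge.
#'
#' @return A data.frame with one row per element key and columns
#'   \code{element}, \code{mass}, \code{vdw_radius}, \code{vdw_volume},
#'   \code{electronegativity}, \code{polarizability},
#'   \code{ionization_potential}, \code{electron_affinity},
#'   \code{covalent_radius}.
#' @examples
#' tab <- property_table()
#' tab[tab$element == "C", ]
#' @export
property_table <- function() {
  ua_mass <- c(CH = 13.019, CH2 = 14.027, CH3 = 15.035, CH4 = 16.043)
  el <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", names(ua_mass))
  mass <- c(1.008, 12.011, 14.007, 15.999, 18.998, 30.974, 32.060,
            35.450, 79.904, 126.904, ua_mass)
  rvdw <- c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98,
            rep(1.70, 4))
  # static dipole polarizabilities (A^3), CRC values
  pol <- c(0.667, 1.760, 1.100, 0.802, 0.557, 3.630, 2.900, 2.180,
           3.050, 5.350, rep(1.760, 4))
  en <- c(2.20, 2.55, 3.04, 3.44, 3.98, 2.19, 2.58, 3.16, 2.96, 2.66,
          rep(2.55, 4))
  ip <- c(13.598, 11.260, 14.534, 13.618, 17.423, 10.487, 10.360,
          12.968, 11.814, 10.451, rep(11.260, 4))
  ea <- c(0.754, 1.262, -0.070, 1.461, 3.401, 0.746, 2.077, 3.613,
          3.364, 3.059, rep(1.262, 4))
  rcov <- c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02, 1.20, 1.39,
            rep(0.76, 4))
  data.frame(
    element = el,
    mass = unname(mass),
    vdw_radius = rvdw,
    vdw_volume = (4 / 3) * pi * rvdw^3,
    electronegativity = en,
    polarizability = pol,
    ionization_potential = ip,
    electron_affinity = ea,
    covalent_radius = rcov,
    stringsAsFactors = FALSE
  )
}

# masses of the united-atom carbon pseudo-elements recognised by
# infer_element(); kept separate so exact UA masses win over the 0.5 g/mol
# element window (CH2 at 14.027 would otherwise collide with N at 14.007)
.ua_masses <- c(CH = 13.019, CH2 = 14.027, CH3 = 15.035, CH4 = 16.043)

#' Infer an element key from an atomic mass
#'
#' Maps a per-type mass from the Masses section of a data file to an element
#' key of \code{\link{property_table}}.  An exact united-atom mass
#' (within 0.005 g/mol of CH, CH2, CH3 or CH4) is matched first; otherwise
#' the element whose standard atomic weight lies within 0.5 g/mol is
#' returned; otherwise a united-atom entry within 0.5 g/mol; otherwise an
#' error is raised naming the offending mass.
#'
#' @param mass Atomic (or united-atom) mass in g/mol; must be positive.
#' @return A single element key, e.g. \code{"C"} or \code{"CH3"}.
#' @examples
#' infer_element(12.011)  # "C"
#' infer_element(15.035)  # "CH3"
#' @export
infer_element <- function(mass) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0)
  d_ua <- abs(.ua_masses - mass)
  if (min(d_ua) < 0.005) return(names(.ua_masses)[which.min(d_ua)])
  tab <- property_table()
  elem <- tab[!tab$element %in% names(.ua_masses), ]
  d_el <- abs(elem$mass - mass)
  if (min(d_el) <= 0.5) return(elem$element[which.min(d_el)])
  if (min(d_ua) <= 0.5) return(names(.ua_masses)[which.min(d_ua)])
  stop("UnknownMass: no element or united-atom entry within 0.5 g/mol of ",
       format(mass), call. = FALSE)
}

# property vectors for a vector of element keys, scaled relative to carbon
# for every property except charge (which is not stored here).  Returns a
# data.frame of raw and carbon-scaled columns used by descriptor modules.
atom_properties <- function(elements) {
  tab <- property_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    stop("unknown element key(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  p <- tab[idx, , drop = FALSE]
  cref <- tab[tab$element == "C", ]
  data.frame(
    element = p$element,
    mass = p$mass,
    vdw_radius = p$vdw_radius,
    vdw_volume = p$vdw_volume,
    electronegativity = p$electronegativity,
    polarizability = p$polarizability,
    ionization_potential = p$ionization_potential,
    electron_affinity = p$electron_affinity,
    covalent_radius = p$covalent_radius,
    w_mass = p$mass / cref$mass,
    w_vdw_volume = p$vdw_volume / cref$vdw_volume,
    w_electronegativity = p$electronegativity / cref$electronegativity,
    w_polarizability = p$polarizability / cref$polarizability,
    w_ionization_potential = p$ionization_potential / cref$ionization_potential,
    w_electron_affinity = p$electron_affinity / cref$electron_affinity,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
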