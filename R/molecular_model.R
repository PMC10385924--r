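#' Build the static system topology from a parsed data file
#'
#' Partitions atoms by molecule id, builds each molecule's bond graph,
#' computes all-pairs topological distances (bond counts, breadth-first)
#' and attaches element keys and physicochemical property vectors inferred
#' from the Masses section via \code{\link{infer_element}}.
#'
#' @param data Result of \code{\link{parse_data}}.
#' @return A list of class \code{system_topology} with \code{atoms}
#'   (data.frame: \code{id}, \code{mol}, \code{type}, \code{q},
#'   \code{element}, \code{mass}, property and carbon-scaled weight
#'   columns) and \code{molecules}, a named list (by molecule id) holding
#'   \code{atom_ids}, \code{bonds} (2-column matrix of atom ids),
#'   \code{adjacency} and \code{d_top} (topological distance matrix), both
#'   indexed in \code{atom_ids} order.
#' @export
build_topology <- function(data) {
  atoms <- data$atoms
  type_elem <- vapply(data$masses$mass, infer_element, "")
  type_mass <- data$masses$mass
  ti <- match(atoms$type, data$masses$type)
  atoms$element <- type_elem[ti]
  atoms$mass <- type_mass[ti]
  props <- atom_properties(atoms$element)
  props$mass <- atoms$mass  # UA pseudo-atoms keep the force-field mass
  atoms <- cbind(atoms[c("id", "mol", "type", "q")],
                 props[c("element", "mass", "vdw_radius", "vdw_volume",
                         "electronegativity", "polarizability",
                         "ionization_potential", "electron_affinity")],
                 props[c("w_mass", "w_vdw_volume", "w_electronegativity",
                         "w_polarizability", "w_ionization_potential",
                         "w_electron_affinity")])
  # mass weight uses the actual per-atom mass over carbon's
  atoms$w_mass <- atoms$mass / property_table()$mass[
    property_table()$element == "C"]

  mol_of <- atoms$mol[match(data$bonds$i, atoms$id)]
  mol_of_j <- atoms$mol[match(data$bonds$j, atoms$id)]
  if (any(mol_of != mol_of_j)) {
    bad <- which(mol_of != mol_of_j)[1]
    stop("DisconnectedMolecule: bond ", data$bonds$id[bad],
         " joins atoms of molecules ", mol_of[bad], " and ", mol_of_j[bad],
         call. = FALSE)
  }

  mol_ids <- sort(unique(atoms$mol))
  molecules <- vector("list", length(mol_ids))
  names(molecules) <- as.character(mol_ids)
  for (m in seq_along(mol_ids)) {
    mid <- mol_ids[m]
    aid <- sort(atoms$id[atoms$mol == mid])
    n <- length(aid)
    bsel <- data$bonds[mol_of == mid, , drop = FALSE]
    adj <- matrix(0L, n, n)
    if (nrow(bsel)) {
      bi <- match(bsel$i, aid); bj <- match(bsel$j, aid)
      adj[cbind(bi, bj)] <- 1L
      adj[cbind(bj, bi)] <- 1L
    }
    if (n > 1) {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)
      if (comp$no > 1) {
        stop("DisconnectedMolecule: molecule ", mid, " has ", comp$no,
             " components of sizes ", paste(comp$csize, collapse = ", "),
             call. = FALSE)
      }
      d_top <- igraph::distances(g)
    } else {
      d_top <- matrix(0, 1, 1)
    }
    dimnames(d_top) <- NULL
    molecules[[m]] <- list(
      mol = mid, atom_ids = aid,
      bonds = cbind(i = bsel$i, j = bsel$j),
      adjacency = adj, d_top = d_top
    )
  }
  structure(list(atoms = atoms, molecules = molecules),
            class = "system_topology")
}

#' Unwrap a trajectory frame across periodic boundaries
#'
#' Returns per-molecule unwrapped coordinates for one dump frame.  Frames
#' dumped with unwrapped coordinates pass through unchanged.  Wrapped
#' coordinates are reconstructed per molecule by a breadth-first traversal
#' of the bond graph from the lowest atom id: each newly reached atom is
#' placed at the minimum-image position relative to its already placed
#' neighbour, i.e. shifted by whole box lengths so every bond displacement
#' component lies in [-L/2, L/2).  The result is exact up to a
#' whole-molecule lattice translation, which leaves every descriptor
#' unchanged.
#'
#' @param frame One frame from \code{\link{parse_dump}}.
#' @param topo Result of \code{\link{build_topology}}.
#' @return Named list (by molecule id) of N x 3 coordinate matrices, rows
#'   in ascending atom-id order.
#' @export
unwrap_frame <- function(frame, topo) {
  L <- frame$box[, "hi"] - frame$box[, "lo"]
  if (any(L <= 0)) stop("NonOrthogonalBox: degenerate box bounds",
                        call. = FALSE)
  coords <- as.matrix(frame$atoms[c("x", "y", "z")])
  rownames(coords) <- frame$atoms$id
  out <- vector("list", length(topo$molecules))
  names(out) <- names(topo$molecules)
  for (m in seq_along(topo$molecules)) {
    mol <- topo$molecules[[m]]
    X <- coords[as.character(mol$atom_ids), , drop = FALSE]
    if (frame$coord_kind == "unwrapped") {
      out[[m]] <- X
      next
    }
    n <- nrow(X)
    placed <- rep(FALSE, n)
    placed[1] <- TRUE  # atom_ids sorted: index 1 is the lowest id
    queue <- 1L
    adj <- mol$adjacency
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] == 1L & !placed)
      for (j in nb) {
        d <- X[j, ] - X[i, ]
        shift <- round(d / L)
        X[j, ] <- X[j, ] - shift * L
        d2 <- X[j, ] - X[i, ]
        # a minimum-image bond approaching half the box cannot be told
        # apart from its periodic alias; refuse rather than guess
        if (sqrt(sum(d2^2)) >= 0.45 * min(L)) {
          stop("BondLongerThanHalfBox: bond ", mol$atom_ids[i], "-",
               mol$atom_ids[j], " approaches half the box; unwrapping is ",
               "ambiguous", call. = FALSE)
        }
        placed[j] <- TRUE
        queue <- c(queue, j)
      }
    }
    if (!all(placed) && n > 1) {
      stop("DisconnectedMolecule: molecule ", mol$mol,
           " has unreachable atoms during unwrapping", call. = FALSE)
    }
    out[[m]] <- X
  }
  out
}

#' Geometric distance matrix and centred coordinates
#'
#' @param X N x 3 coordinate matrix (Angstrom).
#' @return List with \code{dist} (N x N Euclidean distance matrix) and
#'   \code{centered} (coordinates with unweighted column means removed).
#' @export
geometry_matrices <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 3)
  centered <- sweep(X, 2, colMeans(X))
  d <- as.matrix(stats::dist(X))
  dimnames(d) <- NULL
  list(dist = d, centered = centered)
}

# Assemble a per-molecule per-frame snapshot: unwrapped and centred
# coordinates, geometric distance matrix, and the topology slice the
# descriptor modules need (charges, masses, properties, bond graph,
# topological distances).
molecule_snapshot <- function(mol, coords, topo, timestep = NA_integer_) {
  gm <- geometry_matrices(coords)
  arow <- topo$atoms[match(mol$atom_ids, topo$atoms$id), , drop = FALSE]
  list(
    mol = mol$mol, timestep = timestep,
    coords = as.matrix(coords), centered = gm$centered, dist = gm$dist,
    atom_ids = mol$atom_ids,
    adjacency = mol$adjacency, d_top = mol$d_top,
    bonds_idx = if (nrow(mol$bonds)) {
      cbind(match(mol$bonds[, 1], mol$atom_ids),
            match(mol$bonds[, 2], mol$atom_ids))
    } else matrix(integer(0), 0, 2),
    q = arow$q, mass = arow$mass, element = arow$element,
    vdw_radius = arow$vdw_radius,
    weights = list(
      u = rep(1, nrow(arow)), m = arow$w_mass, c = arow$q,
      v = arow$w_vdw_volume, e = arow$w_electronegativity,
      p = arow$w_polarizability, i = arow$w_ionization_potential,
      a = arow$w_electron_affinity
    )
  )
}
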