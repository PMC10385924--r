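# Engine: orchestrates parsing -> unwrapping -> per-molecule per-frame
# descriptor computation -> one CSV per molecule, plus system density.

# g/cm^3 per (g/mol / A^3): 1e24 / Avogadro, declared to five decimals
DENSITY_CONV <- 1.66054

#' System density of one frame
#'
#' \eqn{\rho = 1.66054 \sum_i m_i / V_{box}} with masses in g/mol and the
#' box volume in cubic Angstrom, giving g/cm^3 ("real" units).
#'
#' @param frame One frame from \code{\link{parse_dump}}.
#' @param topo Result of \code{\link{build_topology}}.
#' @return Density in g/cm^3.
#' @export
system_density <- function(frame, topo) {
  L <- frame$box[, "hi"] - frame$box[, "lo"]
  V <- prod(L)
  if (V <= 0) stop("ZeroVolume: box volume is not positive", call. = FALSE)
  sum(topo$atoms$mass) * DENSITY_CONV / V
}

# descriptor catalogue: ordered column names for a set selection
descriptor_names <- function(sets = 1:6) {
  sets <- sort(unique(sets))
  nm <- character(0)
  if (1 %in% sets) nm <- c(nm, topo3d_names())
  if (2 %in% sets) nm <- c(nm, geometric_names())
  if (3 %in% sets) nm <- c(nm, getaway_names())
  if (4 %in% sets) nm <- c(nm, cpsa_names())
  if (5 %in% sets) nm <- c(nm, whim_names())
  if (6 %in% sets) nm <- c(nm, field3d_names())
  nm
}

#' Compute descriptors for one molecule at one frame
#'
#' Evaluates the selected descriptor sets on a molecule snapshot:
#' 1 = 3D topology/connectivity, 2 = geometric, 3 = GETAWAY, 4 = CPSA,
#' 5 = WHIM, 6 = RDF/MoRSE/autocorrelations.
#'
#' @param snapshot Molecule snapshot (see \code{\link{run_descriptors}}
#'   for the file-based entry point, or build one from a topology and a
#'   coordinate matrix with the internal helpers).
#' @param sets Integer subset of 1..6.
#' @param probe,n_points,polar_threshold CPSA tunables.
#' @return Named numeric vector, columns in fixed set order.
#' @export
compute_descriptors <- function(snapshot, sets = 1:6, probe = 1.4,
                                n_points = 960, polar_threshold = 0.2) {
  sets <- sort(unique(sets))
  stopifnot(length(sets) >= 1, all(sets %in% 1:6))
  out <- numeric(0)
  if (1 %in% sets) out <- c(out, topo3d(snapshot))
  if (2 %in% sets) out <- c(out, geometric_block(snapshot))
  if (3 %in% sets) out <- c(out, getaway_block(snapshot))
  if (4 %in% sets) out <- c(out, cpsa_block(snapshot, probe, n_points,
                                            polar_threshold))
  if (5 %in% sets) {
    wb <- whim_block(snapshot)
    attributes(wb) <- attributes(wb)["names"]
    out <- c(out, wb)
  }
  if (6 %in% sets) out <- c(out, field3d_block(snapshot))
  out
}

# shortest round-trip decimal representation
format_shortest <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == trunc(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

# stable polynomial hash of the descriptor catalogue (hex string)
.catalogue_hash <- function(names) {
  h <- 0
  for (b in utf8ToInt(paste(names, collapse = ","))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full descriptor pipeline on a data file + trajectory
#'
#' Parses the two LAMMPS files, checks their consistency, unwraps every
#' selected frame, computes the requested descriptor sets for every
#' molecule at every frame, and writes one CSV per molecule named
#' \code{molecule_<molID>.csv} (header row; one row per frame with
#' \code{timestep}, \code{density} and the descriptor columns in fixed
#' set order), plus a \code{manifest.json} recording inputs, configuration
#' and the descriptor catalogue hash.  Output bytes are identical for any
#' worker count: work is partitioned by (molecule, frame) and reassembled
#' in deterministic order, and numbers are printed with shortest
#' round-trip formatting.
#'
#' @param data_path LAMMPS data file (atom style "full").
#' @param dump_path LAMMPS text dump trajectory.
#' @param out_dir Output directory (created if needed).
#' @param sets Integer subset of 1..6 (default all).
#' @param workers Parallel worker count (default: detected cores).
#' @param stride Keep every \code{stride}-th frame (default 1).
#' @param probe,n_points,polar_threshold CPSA tunables.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the paths of the written CSV files.
#' @export
run_descriptors <- function(data_path, dump_path, out_dir,
                            sets = 1:6, workers = NULL, stride = 1,
                            probe = 1.4, n_points = 960,
                            polar_threshold = 0.2, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  sets <- sort(unique(sets))
  stopifnot(length(sets) >= 1, all(sets %in% 1:6), stride >= 1)
  if (is.null(workers)) workers <- max(1L, parallel::detectCores())
  stopifnot(workers >= 1)
  data <- parse_data(data_path)
  frames <- parse_dump(dump_path)
  topo <- build_topology(data)
  report <- check_consistency(data, frames)
  frames <- frames[seq(1, length(frames), by = stride)]
  if (!quiet) {
    message("system: ", report$n_molecules, " molecules, ",
            nrow(data$atoms), " atoms, ", length(frames), " frames")
  }

  rho <- vapply(frames, system_density, 0, topo = topo)
  unwrapped <- lapply(frames, unwrap_frame, topo = topo)

  mol_keys <- names(topo$molecules)
  units <- expand.grid(mi = seq_along(mol_keys), fi = seq_along(frames),
                       KEEP.OUT.ATTRS = FALSE)
  work <- function(u) {
    mol <- topo$molecules[[units$mi[u]]]
    snap <- molecule_snapshot(mol, unwrapped[[units$fi[u]]][[units$mi[u]]],
                              topo, frames[[units$fi[u]]]$timestep)
    compute_descriptors(snap, sets, probe, n_points, polar_threshold)
  }
  results <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(units)), work, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(units)), work)
  }
  errs <- vapply(results, inherits, TRUE, what = "try-error")
  if (any(errs)) stop(attr(results[[which(errs)[1]]], "condition"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cols <- descriptor_names(sets)
  header <- paste(c("timestep", "density", cols), collapse = ",")
  paths <- character(length(mol_keys))
  for (m in seq_along(mol_keys)) {
    rows <- vapply(seq_along(frames), function(f) {
      vals <- results[[(f - 1) * length(mol_keys) + m]]
      paste(c(format_shortest(c(frames[[f]]$timestep, rho[f])),
              format_shortest(unname(vals[cols]))), collapse = ",")
    }, "")
    path <- file.path(out_dir, paste0("molecule_", mol_keys[m], ".csv"))
    tmp <- paste0(path, ".tmp")
    writeLines(c(header, rows), tmp)
    file.rename(tmp, path)
    paths[m] <- path
  }

  manifest <- list(
    data_file = basename(data_path), dump_file = basename(dump_path),
    sets = sets, stride = stride, workers = workers,
    sasa = list(probe_radius = probe, n_points = n_points),
    cpsa = list(polar_charge_threshold = polar_threshold),
    n_molecules = report$n_molecules, n_frames = length(frames),
    package_version = as.character(utils::packageVersion("trajdescr")),
    descriptor_catalogue_hash = .catalogue_hash(cols)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!quiet) {
    message(sprintf("wrote %d molecule tables (%d columns) in %.2f s",
                    length(paths), length(cols) + 2,
                    proc.time()[["elapsed"]] - t0))
  }
  invisible(paths)
}
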