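#' @importFrom stats setNames
NULL

# strip "#" comments and surrounding whitespace
.strip_comment <- function(x) {
  x <- sub("#.*$", "", x)
  trimws(x)
}

.split_fields <- function(x) strsplit(trimws(x), "[[:space:]]+")[[1]]

# section names recognised in a data file; Coeff sections are skipped
.body_sections <- c("Masses", "Atoms", "Bonds", "Angles", "Dihedrals",
                    "Impropers", "Velocities")
.coeff_re <- "Coeffs?$"

#' Parse a LAMMPS data file (atom style "full")
#'
#' Reads the header (counts and box bounds) and the Masses, Atoms and Bonds
#' sections, plus Angles/Dihedrals/Impropers when present.  Sections are
#' detected by name and may appear in any order; Coeff sections are skipped;
#' comments after \code{#} are ignored; Windows and Unix line endings are
#' both tolerated.  Atoms rows must follow atom style "full"
#' (\code{id mol type charge x y z}, optionally followed by three integer
#' image flags, which are retained).
#'
#' @param path Path to the data file.
#' @return A list of class \code{lammps_data} with elements \code{masses}
#'   (data.frame \code{type}, \code{mass}), \code{atoms} (data.frame
#'   \code{id}, \code{mol}, \code{type}, \code{q}, \code{x}, \code{y},
#'   \code{z} and, when present, \code{ix}, \code{iy}, \code{iz}),
#'   \code{bonds} (data.frame \code{id}, \code{type}, \code{i}, \code{j}),
#'   optional \code{angles}/\code{dihedrals} data.frames, and \code{box}
#'   (3x2 matrix of lo/hi bounds in Angstrom).
#' @export
parse_data <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- gsub("\r$", "", raw)
  if (length(raw) > 0) raw <- raw[-1]  # first line is a free-form title

  counts <- list()
  box <- matrix(NA_real_, 3, 2, dimnames = list(c("x", "y", "z"), c("lo", "hi")))

  # locate section headers
  clean <- vapply(raw, .strip_comment, "", USE.NAMES = FALSE)
  is_header <- clean %in% .body_sections | grepl(.coeff_re, clean)
  header_at <- which(is_header)

  # header zone: everything before the first section
  hdr_end <- if (length(header_at)) header_at[1] - 1L else length(raw)
  for (ln in clean[seq_len(hdr_end)]) {
    if (!nzchar(ln)) next
    f <- .split_fields(ln)
    n <- length(f)
    if (n >= 2 && f[n] %in% c("atoms", "bonds", "angles", "dihedrals",
                              "impropers", "types")) {
      key <- if (f[n] == "types") paste(f[n - 1], f[n]) else f[n]
      counts[[key]] <- as.integer(f[1])
    } else if (n == 4 && f[3] == "xlo" && f[4] == "xhi") {
      box["x", ] <- as.numeric(f[1:2])
    } else if (n == 4 && f[3] == "ylo" && f[4] == "yhi") {
      box["y", ] <- as.numeric(f[1:2])
    } else if (n == 4 && f[3] == "zlo" && f[4] == "zhi") {
      box["z", ] <- as.numeric(f[1:2])
    } else if (any(f %in% c("xy", "xz", "yz"))) {
      stop("NonOrthogonalBox: triclinic tilt factors are not supported",
           call. = FALSE)
    }
  }

  # carve out each section body (up to the next header)
  bodies <- list()
  if (length(header_at)) {
    bounds <- c(header_at, length(raw) + 1L)
    for (k in seq_along(header_at)) {
      nm <- clean[header_at[k]]
      lines_k <- raw[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
      lines_idx <- seq(bounds[k] + 1L, bounds[k + 1L] - 1L)
      body <- .strip_comment(lines_k)
      keep <- nzchar(body)
      if (grepl(.coeff_re, nm)) next
      bodies[[nm]] <- list(text = body[keep], lineno = lines_idx[keep] + 1L)
    }
  }

  for (need in c("Masses", "Atoms", "Bonds")) {
    if (is.null(bodies[[need]])) {
      stop("MissingSection: ", need, call. = FALSE)
    }
  }

  parse_num_table <- function(section, ncol_min, ncol_max, what) {
    b <- bodies[[section]]
    rows <- lapply(seq_along(b$text), function(i) {
      f <- .split_fields(b$text[i])
      if (length(f) < ncol_min || length(f) > ncol_max) {
        stop("MalformedRecord: ", section, " line ", b$lineno[i],
             ": expected ", ncol_min,
             if (ncol_max > ncol_min) paste0("-", ncol_max) else "",
             " fields, found ", length(f), call. = FALSE)
      }
      as.numeric(f)
    })
    rows
  }

  m_rows <- parse_num_table("Masses", 2, 2)
  masses <- data.frame(
    type = as.integer(vapply(m_rows, `[`, 0, 1)),
    mass = vapply(m_rows, `[`, 0, 2)
  )

  a_rows <- parse_num_table("Atoms", 7, 10)
  a_len <- lengths(a_rows)
  if (length(unique(a_len)) > 1) {
    stop("MalformedRecord: Atoms rows have inconsistent field counts",
         call. = FALSE)
  }
  am <- do.call(rbind, a_rows)
  atoms <- data.frame(
    id = as.integer(am[, 1]), mol = as.integer(am[, 2]),
    type = as.integer(am[, 3]), q = am[, 4],
    x = am[, 5], y = am[, 6], z = am[, 7]
  )
  if (ncol(am) == 10) {
    atoms$ix <- as.integer(am[, 8])
    atoms$iy <- as.integer(am[, 9])
    atoms$iz <- as.integer(am[, 10])
  }

  b_rows <- parse_num_table("Bonds", 4, 4)
  bm <- do.call(rbind, b_rows)
  bonds <- data.frame(id = as.integer(bm[, 1]), type = as.integer(bm[, 2]),
                      i = as.integer(bm[, 3]), j = as.integer(bm[, 4]))

  out <- list(masses = masses, atoms = atoms, bonds = bonds, box = box)

  for (sec in c("Angles", "Dihedrals")) {
    if (!is.null(bodies[[sec]])) {
      nfield <- if (sec == "Angles") 5 else 6
      rows <- parse_num_table(sec, nfield, nfield)
      sm <- do.call(rbind, rows)
      df <- as.data.frame(sm)
      names(df) <- c("id", "type", paste0("a", seq_len(nfield - 2)))
      out[[tolower(sec)]] <- df
    }
  }

  # integrity checks
  for (key in c("atoms", "bonds")) {
    if (!is.null(counts[[key]]) && counts[[key]] != nrow(out[[key]])) {
      stop("CountMismatch: header declares ", counts[[key]], " ", key,
           " but ", nrow(out[[key]]), " rows found", call. = FALSE)
    }
  }
  if (anyDuplicated(atoms$id)) {
    stop("MalformedRecord: duplicate atom ids in Atoms section", call. = FALSE)
  }
  if (!all(c(bonds$i, bonds$j) %in% atoms$id)) {
    stop("MalformedRecord: bond endpoint refers to an undeclared atom id",
         call. = FALSE)
  }
  if (!all(atoms$type %in% masses$type)) {
    stop("MalformedRecord: atom type missing from Masses section",
         call. = FALSE)
  }
  if (!all(is.na(box)) && any(box[, "hi"] <= box[, "lo"])) {
    stop("MalformedRecord: box hi must exceed lo on every axis", call. = FALSE)
  }
  class(out) <- "lammps_data"
  out
}

#' Parse a LAMMPS text dump trajectory
#'
#' Reads all frames of a text dump (\code{ITEM: TIMESTEP} /
#' \code{ITEM: BOX BOUNDS} / \code{ITEM: ATOMS ...} blocks).  Column
#' positions are resolved from the ATOMS header line of each frame, never
#' assumed, so any column order written by LAMMPS is accepted.  Records are
#' sorted by atom id within each frame.  Coordinates may be wrapped
#' (\code{x y z}) or unwrapped (\code{xu yu zu}); scaled coordinates
#' (\code{xs ys zs}) are rejected.
#'
#' @param path Path to the dump file.
#' @return A list of frames, each a list with \code{timestep},
#'   \code{box} (3x2 lo/hi matrix), \code{periodic} (logical length-3),
#'   \code{coord_kind} (\code{"wrapped"} or \code{"unwrapped"}) and
#'   \code{atoms} (data.frame \code{id}, \code{mol}, \code{type},
#'   \code{x}, \code{y}, \code{z}, sorted by \code{id}; plus \code{q}
#'   when the dump carries charges).
#' @export
parse_dump <- function(path) {
  if (!file.exists(path)) stop("dump file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- gsub("\r$", "", raw)
  item_at <- grep("^ITEM: TIMESTEP", raw)
  if (!length(item_at)) stop("TruncatedFrame: no ITEM: TIMESTEP found",
                             call. = FALSE)
  frames <- vector("list", length(item_at))
  bounds <- c(item_at, length(raw) + 1L)
  for (k in seq_along(item_at)) {
    block <- raw[seq(bounds[k], bounds[k + 1L] - 1L)]
    frames[[k]] <- .parse_dump_frame(block)
  }
  natoms <- vapply(frames, function(f) nrow(f$atoms), 0L)
  if (length(unique(natoms)) > 1) {
    stop("TruncatedFrame: atom count varies across frames", call. = FALSE)
  }
  frames
}

.parse_dump_frame <- function(block) {
  get_after <- function(pattern, n) {
    at <- grep(pattern, block)
    if (!length(at) || at[1] + n > length(block)) {
      stop("TruncatedFrame: missing ", pattern, call. = FALSE)
    }
    block[at[1] + seq_len(n)]
  }
  timestep <- as.integer(.split_fields(get_after("^ITEM: TIMESTEP", 1))[1])

  box_hdr_at <- grep("^ITEM: BOX BOUNDS", block)
  if (!length(box_hdr_at)) stop("TruncatedFrame: missing BOX BOUNDS",
                                call. = FALSE)
  box_hdr <- .split_fields(sub("^ITEM: BOX BOUNDS", "", block[box_hdr_at[1]]))
  if (any(c("xy", "xz", "yz") %in% box_hdr)) {
    stop("NonOrthogonalBox: triclinic dump boxes are not supported",
         call. = FALSE)
  }
  periodic <- if (length(box_hdr) >= 3) box_hdr[1:3] == "pp" else rep(TRUE, 3)
  box_lines <- get_after("^ITEM: BOX BOUNDS", 3)
  box <- t(vapply(box_lines, function(l) as.numeric(.split_fields(l))[1:2],
                  c(0, 0), USE.NAMES = FALSE))
  dimnames(box) <- list(c("x", "y", "z"), c("lo", "hi"))

  atoms_hdr_at <- grep("^ITEM: ATOMS", block)
  if (!length(atoms_hdr_at)) stop("TruncatedFrame: missing ITEM: ATOMS",
                                  call. = FALSE)
  cols <- .split_fields(sub("^ITEM: ATOMS", "", block[atoms_hdr_at[1]]))
  for (need in c("id", "mol", "type")) {
    if (!need %in% cols) stop("MissingColumn: ", need, call. = FALSE)
  }
  has_w <- all(c("x", "y", "z") %in% cols)
  has_u <- all(c("xu", "yu", "zu") %in% cols)
  if (any(c("xs", "ys", "zs") %in% cols)) {
    stop("MissingColumn: scaled coordinates (xs ys zs) are not supported; ",
         "dump x y z or xu yu zu", call. = FALSE)
  }
  if (has_w && has_u) {
    stop("MixedCoordinateKinds: dump carries both x/y/z and xu/yu/zu",
         call. = FALSE)
  }
  if (!has_w && !has_u) stop("MissingColumn: coordinates", call. = FALSE)
  coord_kind <- if (has_u) "unwrapped" else "wrapped"
  cxyz <- if (has_u) c("xu", "yu", "zu") else c("x", "y", "z")

  body <- block[seq(atoms_hdr_at[1] + 1L, length(block))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("TruncatedFrame: no atom records", call. = FALSE)
  mat <- do.call(rbind, lapply(body, function(l) {
    f <- .split_fields(l)
    if (length(f) != length(cols)) {
      stop("TruncatedFrame: atom record has ", length(f),
           " fields, header declares ", length(cols), call. = FALSE)
    }
    as.numeric(f)
  }))
  colnames(mat) <- cols
  atoms <- data.frame(
    id = as.integer(mat[, "id"]), mol = as.integer(mat[, "mol"]),
    type = as.integer(mat[, "type"]),
    x = mat[, cxyz[1]], y = mat[, cxyz[2]], z = mat[, cxyz[3]]
  )
  if ("q" %in% cols) atoms$q <- mat[, "q"]
  if (anyDuplicated(atoms$id)) {
    stop("TruncatedFrame: duplicate atom ids within a frame", call. = FALSE)
  }
  atoms <- atoms[order(atoms$id), , drop = FALSE]
  rownames(atoms) <- NULL
  list(timestep = timestep, box = box, periodic = periodic,
       coord_kind = coord_kind, atoms = atoms)
}

#' Check that a data file and a trajectory describe the same system
#'
#' Verifies that the atom-id set of every dump frame matches the data file
#' and summarises the molecular composition.
#'
#' @param data Result of \code{\link{parse_data}}.
#' @param frames Result of \code{\link{parse_dump}}.
#' @return A list with \code{n_molecules}, \code{molecule_ids} and
#'   \code{atoms_per_molecule} (named integer vector).
#' @export
check_consistency <- function(data, frames) {
  ids <- sort(data$atoms$id)
  for (k in seq_along(frames)) {
    fid <- sort(frames[[k]]$atoms$id)
    if (!identical(as.integer(ids), as.integer(fid))) {
      bad <- union(setdiff(fid, ids), setdiff(ids, fid))
      stop("AtomSetMismatch: frame ", k, " differs from data file; ",
           "offending atom ids: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  per_mol <- table(data$atoms$mol)
  list(
    n_molecules = length(per_mol),
    molecule_ids = as.integer(names(per_mol)),
    atoms_per_molecule = setNames(as.integer(per_mol), names(per_mol))
  )
}
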