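# Structures are stored as a plain atom table (data.frame) wrapped in class
# "fibril_structure"; trajectories as class "fibril_trajectory" holding one
# topology plus a frames x atoms x 3 coordinate array. Internal length unit
# is nm everywhere; PDB files are Angstrom and converted at this boundary.

new_structure <- function(atoms, title = "") {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "fibril_structure")
}

#' @export
print.fibril_structure <- function(x, ...) {
  cat("fibril_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' @export
print.fibril_trajectory <- function(x, ...) {
  cat("fibril_trajectory:", dim(x$coords)[1], "frames x",
      dim(x$coords)[2], "atoms; t =", x$times[1], "..",
      x$times[length(x$times)], "ns\n")
  invisible(x)
}

parse_pdb_atoms <- function(lines, keep_het = FALSE) {
  is_atom <- startsWith(lines, "ATOM  ") | (keep_het & startsWith(lines, "HETATM"))
  idx <- which(is_atom)
  if (length(idx) == 0) return(NULL)
  rec <- lines[idx]
  bad <- which(nchar(rec) < 54)
  if (length(bad) > 0) {
    stop("malformed ATOM record at line ", idx[bad[1]], ": too short")
  }
  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    b <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("malformed ATOM record at line ", idx[b], ": unreadable coordinates")
  }
  occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    name    = trimws(substr(rec, 13, 16)),
    altloc  = substr(rec, 17, 17),
    resname = trimws(substr(rec, 18, 20)),
    chain   = substr(rec, 22, 22),
    resid   = as.integer(substr(rec, 23, 26)),
    x = x / 10, y = y / 10, z = z / 10,   # Angstrom -> nm
    occ = occ,
    element = trimws(substr(rec, 77, 78)),
    stringsAsFactors = FALSE
  )
}

resolve_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c(" ", ""))) {
    atoms$altloc <- NULL
    return(atoms)
  }
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), factor(key, levels = unique(key))),
                        function(i) i[which.max(atoms$occ[i])]), use.names = FALSE)
  atoms <- atoms[sort(keep), ]
  atoms$altloc <- NULL
  atoms
}

guess_element <- function(name) {
  el <- sub("^[0-9]*", "", name)
  substr(el, 1, 1)
}

#' Read a structure from a PDB file
#'
#' Coordinates are converted from Angstrom to nm. Alternate locations are
#' resolved to the highest occupancy; waters and heteroatoms are dropped
#' unless requested.
#'
#' @param path Path to a PDB file.
#' @param keep_het Keep HETATM records (default `FALSE`).
#' @return A `fibril_structure`: list with an `atoms` data.frame
#'   (`name`, `resname`, `chain`, `resid`, `x`, `y`, `z` in nm, `element`).
#' @export
read_structure <- function(path, keep_het = FALSE) {
  lines <- readLines(path, warn = FALSE)
  atoms <- parse_pdb_atoms(lines, keep_het = keep_het)
  if (is.null(atoms)) stop("no ATOM records in ", path)
  atoms <- resolve_altloc(atoms)
  atoms <- atoms[atoms$resname != "HOH", ]
  miss <- atoms$element == ""
  atoms$element[miss] <- guess_element(atoms$name[miss])
  atoms$occ <- NULL
  new_structure(atoms, title = basename(path))
}

format_atom_line <- function(i, a) {
  # PDB atom names: element right-justified in cols 13-14 for 1-2 char names
  nm <- a$name[i]
  nm_f <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          (i - 1L) %% 99999L + 1L, nm_f, a$resname[i], a$chain[i], a$resid[i],
          a$x[i] * 10, a$y[i] * 10, a$z[i] * 10, 1, 0, a$element[i])
}

write_atoms <- function(atoms, con) {
  n <- nrow(atoms)
  lines <- vapply(seq_len(n), format_atom_line, character(1), a = atoms)
  writeLines(lines, con)
}

#' Write a structure to a PDB file
#' @param structure A `fibril_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", structure$title), con)
  write_atoms(structure$atoms, con)
  writeLines(c("TER", "END"), con)
  invisible(path)
}

new_trajectory <- function(topology, coords, times) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(topology$atoms)) {
    stop("coordinate array atom count does not match topology")
  }
  if (length(times) != dim(coords)[1]) stop("times length must equal frame count")
  if (length(times) > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "fibril_trajectory")
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; all models must share one atom
#' table. A file without MODEL records is read as a single-frame trajectory.
#'
#' @param path Path to a (multi-model) PDB file.
#' @param dt_ns Frame stride in ns (frame times are `0, dt, 2*dt, ...`).
#' @return A `fibril_trajectory` with `topology`, `coords`
#'   (frames x atoms x 3, nm) and `times` (ns).
#' @export
read_trajectory <- function(path, dt_ns = 1) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts) == 0) {
    s <- read_structure(path)
    coords <- array(as.matrix(s$atoms[, c("x", "y", "z")]),
                    dim = c(1, nrow(s$atoms), 3))
    return(new_trajectory(s, coords, 0))
  }
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  frames <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    blk <- parse_pdb_atoms(lines[starts[m]:ends[m]])
    if (is.null(blk)) stop("model ", m, " has no ATOM records")
    frames[[m]] <- blk
  }
  n0 <- nrow(frames[[1]])
  for (m in seq_along(frames)) {
    if (nrow(frames[[m]]) != n0) {
      stop("model ", m, " has ", nrow(frames[[m]]), " atoms; expected ", n0)
    }
  }
  topo_atoms <- resolve_altloc(frames[[1]])
  miss <- topo_atoms$element == ""
  topo_atoms$element[miss] <- guess_element(topo_atoms$name[miss])
  topo_atoms$occ <- NULL
  topo <- new_structure(topo_atoms, title = basename(path))
  coords <- array(0, dim = c(length(frames), n0, 3))
  for (m in seq_along(frames)) {
    coords[m, , ] <- as.matrix(frames[[m]][, c("x", "y", "z")])
  }
  new_trajectory(topo, coords, dt_ns * (seq_along(frames) - 1))
}

#' Write a trajectory as a multi-model PDB file
#' @param traj A `fibril_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", traj$topology$title), con)
  atoms <- traj$topology$atoms
  for (m in seq_len(dim(traj$coords)[1])) {
    writeLines(sprintf("MODEL     %4d", m), con)
    atoms$x <- traj$coords[m, , 1]
    atoms$y <- traj$coords[m, , 2]
    atoms$z <- traj$coords[m, , 3]
    write_atoms(atoms, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract one frame of a trajectory as a structure
#' @param traj A `fibril_trajectory`.
#' @param frame Frame index (1-based).
#' @return A `fibril_structure`.
#' @export
get_frame <- function(traj, frame) {
  atoms <- traj$topology$atoms
  atoms$x <- traj$coords[frame, , 1]
  atoms$y <- traj$coords[frame, , 2]
  atoms$z <- traj$coords[frame, , 3]
  new_structure(atoms, title = sprintf("%s frame %d", traj$topology$title, frame))
}

#' Build a trajectory in memory from a structure and a coordinate array
#' @param structure Topology (`fibril_structure`).
#' @param coords Frames x atoms x 3 array (nm) or a list of atoms x 3 matrices.
#' @param times Frame times in ns.
#' @return A `fibril_trajectory`.
#' @export
make_trajectory <- function(structure, coords, times) {
  if (is.list(coords)) {
    arr <- array(0, dim = c(length(coords), nrow(structure$atoms), 3))
    for (i in seq_along(coords)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  new_trajectory(structure, coords, times)
}

# Cα coordinate matrix of a structure (optionally one chain), rows in
# residue order
ca_coords <- function(structure, chain = NULL) {
  a <- structure$atoms
  sel <- a$name == "CA"
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

# indices (rows of the atom table) of Cα atoms
ca_indices <- function(structure, chain = NULL) {
  a <- structure$atoms
  sel <- a$name == "CA"
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  which(sel)
}
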