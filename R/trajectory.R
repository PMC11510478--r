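#' Build a trajectory object
#'
#' A `trajectory` is the package's in-memory representation of a structure
#' plus a series of coordinate frames. The topology is a data frame of atoms
#' (one row per atom) and the coordinates are stored as an
#' `n_atoms x 3 x n_frames` array in ångström, index-aligned with the
#' topology rows.
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain` (one row per atom).
#' @param coords Numeric array of dimension `c(n_atoms, 3, n_frames)`, or an
#'   `n_atoms x 3` matrix for a single frame. Units: ångström.
#' @param times Numeric vector of frame times in picoseconds, non-decreasing.
#'
#' @return An object of class `trajectory` with elements `atoms`, `coords`
#'   and `times`.
#' @export
trajectory <- function(atoms, coords, times = NULL) {
  required <- c("serial", "name", "element", "resname", "resno", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms[required], stringsAsFactors = FALSE)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  for (col in c("name", "element", "resname", "chain")) {
    atoms[[col]] <- as.character(atoms[[col]])
  }

  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(atoms)) {
    stop("coords has ", dim(coords)[1], " atoms but topology has ", nrow(atoms))
  }
  if (dim(coords)[3] < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("coordinates must all be finite")

  n_frames <- dim(coords)[3]
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1L)
  if (length(times) != n_frames) {
    stop("times has length ", length(times), " but there are ", n_frames, " frames")
  }
  if (is.unsorted(times)) stop("frame times must be non-decreasing")

  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("(chain, resno, name) must be unique; duplicated: ",
         key[which(duplicated(key))[1]])
  }

  structure(list(atoms = atoms, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames (t = %g..%g ps)\n",
              n_atoms(x), n_frames(x), x$times[1], x$times[n_frames(x)]))
  cat("  chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms / frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer count.
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' @rdname n_atoms
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's coordinates as an n x 3 matrix
#' @param traj A [trajectory()].
#' @param frame Frame index (1-based).
#' @return Numeric `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, frame = 1L) {
  if (frame < 1L || frame > n_frames(traj)) {
    stop("frame ", frame, " out of range 1..", n_frames(traj))
  }
  traj$coords[, , frame, drop = TRUE]
}

#' Describe an atom selection
#'
#' A selection is a conjunction of optional predicates over chain id,
#' residue number, residue name and atom name. It resolves to a
#' deterministic, topology-ordered index list via [select_atoms()].
#'
#' @param chain Character vector of chain ids to keep (NULL = any).
#' @param resno Integer vector of residue numbers to keep (NULL = any);
#'   ranges are inclusive at both ends, e.g. `92:157`.
#' @param resname Character vector of residue names (NULL = any).
#' @param name Character vector of atom names (NULL = any).
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(chain = NULL, resno = NULL, resname = NULL, name = NULL) {
  structure(list(chain = chain, resno = resno, resname = resname, name = name),
            class = "atom_selection")
}

#' Resolve a selection to topology indices
#'
#' @param traj A [trajectory()].
#' @param selection An [atom_selection()]; alternatively pass the predicate
#'   fields directly.
#' @inheritParams atom_selection
#' @return Integer vector of atom indices in topology order (possibly empty).
#' @export
select_atoms <- function(traj, selection = NULL, chain = NULL, resno = NULL,
                         resname = NULL, name = NULL) {
  if (!is.null(selection)) {
    if (!inherits(selection, "atom_selection")) {
      stop("selection must be an atom_selection object")
    }
    chain <- selection$chain
    resno <- selection$resno
    resname <- selection$resname
    name <- selection$name
  }
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  which(keep)
}

#' Combine two trajectories over the same frames
#'
#' Concatenates topologies and per-frame coordinates; both inputs must have
#' the same number of frames and identical time stamps. Used to assemble a
#' protein + membrane bundle from the separate synthetic generators.
#'
#' @param a,b [trajectory()] objects with equal frame counts and times.
#' @return A [trajectory()] with `n_atoms(a) + n_atoms(b)` atoms.
#' @export
bind_trajectories <- function(a, b) {
  if (n_frames(a) != n_frames(b)) stop("frame counts differ")
  if (!isTRUE(all.equal(a$times, b$times))) stop("frame times differ")
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  coords <- array(0, dim = c(nrow(atoms), 3L, n_frames(a)))
  coords[seq_len(n_atoms(a)), , ] <- a$coords
  coords[n_atoms(a) + seq_len(n_atoms(b)), , ] <- b$coords
  trajectory(atoms, coords, a$times)
}
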