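# Structure / trajectory readers and writers.
#
# PDB parsing is delegated to bio3d; a validation pre-scan reports malformed
# ATOM/HETATM records with their line number, which bio3d does not. GRO is
# parsed here (fixed-column format, nm converted to angstrom). coord_table
# is the package's plain CSV frame format: columns
# frame,time_ps,atom_index,x,y,z with coordinates in angstrom, written with
# full double precision so a write/read round trip is bit-exact.

infer_element <- function(atom_name) {
  stripped <- gsub("[0-9'\"]", "", trimws(atom_name))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "CA2", "MN", "SE")
  up <- toupper(stripped)
  ifelse(nchar(up) >= 2 & substr(up, 1, 2) %in% two,
         paste0(substr(up, 1, 1), tolower(substr(up, 2, 2))),
         substr(up, 1, 1))
}

validate_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM record at line ", i, ": line too short (",
           nchar(ln), " < 54 characters)")
    }
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz)))) {
      stop("malformed ATOM record at line ", i, ": non-numeric coordinate field")
    }
  }
  invisible(TRUE)
}

pdb_to_trajectory <- function(path, dt = 1) {
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- as.character(at$elesy)
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- infer_element(at$elety[blank])
  chain <- as.character(at$chain)
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(serial = at$eleno, name = at$elety, element = elem,
                      resname = at$resid, resno = at$resno, chain = chain,
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(0, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(atoms, coords, times = (seq_len(nf) - 1) * dt)
}

parse_gro_block <- function(lines, offset) {
  if (length(lines) < 3) stop("GRO block truncated at line ", offset + 1)
  title <- lines[1]
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("invalid GRO atom count at line ", offset + 2)
  if (length(lines) < nat + 3) {
    stop("GRO block starting at line ", offset + 1, " declares ", nat,
         " atoms but the file ends early")
  }
  atom_lines <- lines[3:(nat + 2)]
  resno <- as.integer(substr(atom_lines, 1, 5))
  resname <- trimws(substr(atom_lines, 6, 10))
  name <- trimws(substr(atom_lines, 11, 15))
  serial <- as.integer(substr(atom_lines, 16, 20))
  x <- as.numeric(substr(atom_lines, 21, 28))
  y <- as.numeric(substr(atom_lines, 29, 36))
  z <- as.numeric(substr(atom_lines, 37, 44))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop("malformed GRO atom record at line ", offset + 2 + bad[1])
  }
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  time_ps <- if (length(tm) == 1) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  list(atoms = data.frame(serial = serial, name = name,
                          element = infer_element(name), resname = resname,
                          resno = resno, chain = "A",
                          stringsAsFactors = FALSE),
       coords = cbind(x, y, z) * 10,  # nm -> angstrom
       time = time_ps,
       n_lines = nat + 3)
}

gro_to_trajectory <- function(path, dt = 1) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  atoms <- NULL
  pos <- 0L
  while (pos < length(lines)) {
    if (all(trimws(lines[(pos + 1):length(lines)]) == "")) break
    blk <- parse_gro_block(lines[(pos + 1):length(lines)], pos)
    if (is.null(atoms)) {
      atoms <- blk$atoms
    } else if (nrow(blk$atoms) != nrow(atoms)) {
      stop("GRO frame ", length(frames) + 1L, " has ", nrow(blk$atoms),
           " atoms; expected ", nrow(atoms))
    }
    frames[[length(frames) + 1L]] <- blk
    pos <- pos + blk$n_lines
  }
  if (length(frames) == 0) stop("no GRO frames found in ", path)
  coords <- array(0, dim = c(nrow(atoms), 3L, length(frames)))
  times <- numeric(length(frames))
  for (f in seq_along(frames)) {
    coords[, , f] <- frames[[f]]$coords
    times[f] <- frames[[f]]$time
  }
  if (anyNA(times)) times <- (seq_along(frames) - 1) * dt
  # GRO numbering wraps at 100000 and may repeat residue numbers across
  # molecules; rebuild unique per-chain numbering only if needed.
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) atoms$resno <- seq_len(nrow(atoms))
  atoms$serial <- seq_len(nrow(atoms))
  trajectory(atoms, coords, times)
}

#' Read a structure file into a single-frame trajectory
#'
#' @param path File path.
#' @param format `"pdb"` or `"gro"`. GRO coordinates (nm) are converted to
#'   ångström; PDB coordinates are taken as ångström.
#' @return A [trajectory()] with one frame.
#' @export
read_structure <- function(path, format = c("pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  traj <- switch(format,
                 pdb = pdb_to_trajectory(path),
                 gro = gro_to_trajectory(path))
  if (n_frames(traj) > 1L) {
    traj$coords <- traj$coords[, , 1L, drop = FALSE]
    traj$times <- traj$times[1L]
  }
  traj
}

#' Read a coordinate trajectory
#'
#' @param path File path.
#' @param format One of `"multi_model_pdb"`, `"gro_series"`, `"coord_table"`.
#' @param topology For `coord_table` (which carries no atom metadata): a
#'   [trajectory()], an atoms data frame, or the path of a topology CSV
#'   written by [write_topology_csv()]. If omitted, placeholder atoms are
#'   synthesised.
#' @param dt Frame spacing in ps used when the file carries no time stamps.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("multi_model_pdb", "gro_series",
                                             "coord_table"),
                            topology = NULL, dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         multi_model_pdb = pdb_to_trajectory(path, dt = dt),
         gro_series = gro_to_trajectory(path, dt = dt),
         coord_table = read_coord_table(path, topology = topology))
}

#' Write / read the plain coordinate-table format
#'
#' CSV with header `frame,time_ps,atom_index,x,y,z`, one row per atom per
#' frame, coordinates in ångström printed with 17 significant digits so the
#' round trip is bit-exact.
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coord_table <- function(traj, path) {
  na <- n_atoms(traj)
  nf <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("frame,time_ps,atom_index,x,y,z", con)
  for (f in seq_len(nf)) {
    X <- frame_coords(traj, f)
    writeLines(sprintf("%d,%.17g,%d,%.17g,%.17g,%.17g",
                       f, traj$times[f], seq_len(na),
                       X[, 1], X[, 2], X[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_coord_table
#' @inheritParams read_trajectory
#' @export
read_coord_table <- function(path, topology = NULL) {
  tab <- utils::read.csv(path, colClasses = c(frame = "integer",
                                              time_ps = "numeric",
                                              atom_index = "integer",
                                              x = "numeric", y = "numeric",
                                              z = "numeric"))
  need <- c("frame", "time_ps", "atom_index", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("coord_table must have columns ", paste(need, collapse = ","))
  }
  frames <- sort(unique(tab$frame))
  na <- sum(tab$frame == frames[1])
  coords <- array(0, dim = c(na, 3L, length(frames)))
  times <- numeric(length(frames))
  for (k in seq_along(frames)) {
    sub <- tab[tab$frame == frames[k], , drop = FALSE]
    if (nrow(sub) != na) {
      stop("frame ", frames[k], " has ", nrow(sub), " atoms; expected ", na)
    }
    sub <- sub[order(sub$atom_index), , drop = FALSE]
    coords[, , k] <- cbind(sub$x, sub$y, sub$z)
    times[k] <- sub$time_ps[1]
  }
  atoms <- resolve_topology(topology, na)
  trajectory(atoms, coords, times)
}

resolve_topology <- function(topology, na) {
  if (is.null(topology)) {
    return(data.frame(serial = seq_len(na), name = "X", element = "C",
                      resname = "UNK", resno = seq_len(na), chain = "A",
                      stringsAsFactors = FALSE))
  }
  atoms <- if (inherits(topology, "trajectory")) {
    topology$atoms
  } else if (is.character(topology)) {
    utils::read.csv(topology, colClasses = "character")
  } else {
    topology
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms) != na) {
    stop("topology has ", nrow(atoms), " atoms; coordinate table has ", na)
  }
  atoms
}

#' Write the topology as a CSV sidecar for coord_table files
#' @param traj A [trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_topology_csv <- function(traj, path) {
  utils::write.csv(traj$atoms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a (multi-model) PDB file
#'
#' Coordinates are written at the format's native 3-decimal precision.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  a <- traj$atoms
  multi <- n_frames(traj) > 1L
  for (f in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    X <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial %% 100000L,
      ifelse(nchar(a$name) >= 4, a$name, paste0(" ", a$name)),
      substr(a$resname, 1, 4), substr(a$chain, 1, 1), a$resno %% 10000L,
      X[, 1], X[, 2], X[, 3], toupper(a$element)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
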