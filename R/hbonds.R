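#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair is a hydrogen bond when the donor-acceptor
#' distance is at most `da_cutoff` (inclusive) and the hydrogen-donor-
#' acceptor angle — the deviation from a linear D-H...A arrangement,
#' measured at the donor — is at most `angle_cutoff`. These defaults
#' mirror the convention of the standard MD analysis tools (3.5 ångström,
#' 30 degrees). When the topology carries no hydrogens, detection runs in
#' distance-only mode and the output is labelled accordingly.
#'
#' @param da_cutoff Donor-acceptor distance cutoff, ångström.
#' @param angle_cutoff H-D-A angle cutoff, degrees.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(da_cutoff = 3.5, angle_cutoff = 30) {
  if (da_cutoff <= 0 || angle_cutoff <= 0) stop("cutoffs must be positive")
  structure(list(da_cutoff = da_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

# hydrogens covalently attached to each donor: same chain+residue, element
# H, within 1.2 angstrom.
attached_hydrogens <- function(traj, frame, donors) {
  a <- traj$atoms
  X <- frame_coords(traj, frame)
  hyd <- which(toupper(a$element) == "H")
  out <- vector("list", length(donors))
  for (k in seq_along(donors)) {
    d <- donors[k]
    cand <- hyd[a$chain[hyd] == a$chain[d] & a$resno[hyd] == a$resno[d]]
    if (length(cand) > 0) {
      dd <- sqrt(colSums((t(X[cand, , drop = FALSE]) - X[d, ])^2))
      cand <- cand[dd <= 1.2]
    }
    out[[k]] <- cand
  }
  out
}

#' Detect hydrogen bonds in one frame
#'
#' @param traj A [trajectory()].
#' @param donors Integer indices of donor heavy atoms.
#' @param acceptors Integer indices of acceptor atoms.
#' @param criteria An [hbond_criteria()].
#' @param frame Frame index.
#' @return Data frame with columns `donor`, `hydrogen` (NA in
#'   distance-only mode), `acceptor`, `distance_A`, `angle_deg`, and
#'   attribute `mode` (`"angular"` or `"distance_only"`). Empty donor or
#'   acceptor sets give an empty data frame.
#' @export
detect_hbonds <- function(traj, donors, acceptors,
                          criteria = hbond_criteria(), frame = 1L) {
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance_A = numeric(0),
                      angle_deg = numeric(0))
  if (length(donors) == 0 || length(acceptors) == 0) {
    return(structure(empty, mode = "angular"))
  }
  X <- frame_coords(traj, frame)
  hyds <- attached_hydrogens(traj, frame, donors)
  mode <- if (all(lengths(hyds) == 0)) "distance_only" else "angular"
  rows <- list()
  for (k in seq_along(donors)) {
    d <- donors[k]
    dv <- t(X[acceptors, , drop = FALSE]) - X[d, ]
    dist <- sqrt(colSums(dv^2))
    near <- which(dist <= criteria$da_cutoff & acceptors != d)
    for (j in near) {
      acc <- acceptors[j]
      if (mode == "distance_only") {
        rows[[length(rows) + 1]] <- data.frame(
          donor = d, hydrogen = NA_integer_, acceptor = acc,
          distance_A = dist[j], angle_deg = NA_real_)
      } else {
        hs <- hyds[[k]]
        if (length(hs) == 0) next
        ang <- vapply(hs, function(h) {
          angle_between(X[h, ] - X[d, ], X[acc, ] - X[d, ])
        }, numeric(1))
        best <- which.min(ang)
        if (ang[best] <= criteria$angle_cutoff) {
          rows[[length(rows) + 1]] <- data.frame(
            donor = d, hydrogen = hs[best], acceptor = acc,
            distance_A = dist[j], angle_deg = ang[best])
        }
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  structure(out, mode = mode)
}

#' Define a named residue group (charged cluster)
#'
#' @param name Group label, e.g. `"group1"`.
#' @param members Data frame with columns `chain`, `resno` and optionally
#'   `resname` (checked against the topology when present).
#' @return An object of class `residue_group`.
#' @export
residue_group <- function(name, members) {
  if (nrow(members) == 0) stop("residue group must be non-empty")
  structure(list(name = name, members = members), class = "residue_group")
}

check_group <- function(traj, group) {
  a <- traj$atoms
  for (k in seq_len(nrow(group$members))) {
    m <- group$members[k, ]
    i <- which(a$chain == m$chain & a$resno == m$resno)
    if (length(i) == 0) {
      stop("group ", group$name, ": residue ", m$chain, ":", m$resno,
           " absent from topology")
    }
    if (!is.null(m$resname) && !is.na(m$resname) &&
        !any(a$resname[i] == m$resname)) {
      stop("group ", group$name, ": residue ", m$chain, ":", m$resno,
           " is ", a$resname[i[1]], ", expected ", m$resname)
    }
  }
  invisible(TRUE)
}

#' Per-frame hydrogen-bond counts, grouped by residue cluster
#'
#' Runs [detect_hbonds()] per frame between the donor selection and the
#' lipid acceptors, and tabulates: the total count, the count per residue
#' group (a bond belongs to a group when its donor's (chain, resno) is a
#' member), and the count per acceptor lipid residue name (headgroup
#' partner type).
#'
#' @param traj A [trajectory()].
#' @param groups List of [residue_group()] objects.
#' @param donors Integer indices of donor heavy atoms.
#' @param lipid_sel Integer indices of lipid acceptor atoms (non-empty).
#' @param criteria An [hbond_criteria()].
#' @return List of class `hbond_series`: `counts` (data frame `frame`,
#'   `time_ps`, `total`, one column per group), `by_lipid` (data frame of
#'   per-resname counts), `mode`.
#' @export
grouped_hbond_series <- function(traj, groups, donors, lipid_sel,
                                 criteria = hbond_criteria()) {
  if (length(lipid_sel) == 0) stop("lipid selection is empty")
  for (g in groups) check_group(traj, g)
  a <- traj$atoms
  nf <- n_frames(traj)
  gnames <- vapply(groups, function(g) g$name, character(1))
  counts <- data.frame(frame = seq_len(nf), time_ps = traj$times,
                       total = 0L)
  for (g in gnames) counts[[g]] <- 0L
  lipid_names <- sort(unique(a$resname[lipid_sel]))
  by_lipid <- data.frame(frame = seq_len(nf), time_ps = traj$times)
  for (ln in lipid_names) by_lipid[[ln]] <- 0L
  mode <- "angular"
  for (f in seq_len(nf)) {
    bonds <- detect_hbonds(traj, donors, lipid_sel, criteria, frame = f)
    mode <- attr(bonds, "mode")
    counts$total[f] <- nrow(bonds)
    if (nrow(bonds) == 0) next
    dch <- a$chain[bonds$donor]
    dres <- a$resno[bonds$donor]
    for (gi in seq_along(groups)) {
      m <- groups[[gi]]$members
      counts[[gnames[gi]]][f] <-
        sum(paste(dch, dres) %in% paste(m$chain, m$resno))
    }
    arn <- a$resname[bonds$acceptor]
    for (ln in lipid_names) by_lipid[[ln]][f] <- sum(arn == ln)
  }
  structure(list(counts = counts, by_lipid = by_lipid, mode = mode),
            class = "hbond_series")
}
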