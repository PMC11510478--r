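# RMSD / RMSF over a trajectory. Optimal rigid superposition is delegated
# to bio3d (fit.xyz / rmsd / rmsf) on the package's coordinate arrays.

traj_to_xyz <- function(traj, sel) {
  nf <- n_frames(traj)
  out <- matrix(0, nf, 3 * length(sel))
  for (f in seq_len(nf)) {
    out[f, ] <- as.vector(t(frame_coords(traj, f)[sel, , drop = FALSE]))
  }
  out
}

#' Per-frame RMSD after optimal superposition
#'
#' Least-squares rigid-body superposition of each frame's selected atoms
#' onto the reference, then root-mean-square deviation.
#'
#' @param traj A [trajectory()].
#' @param sel Integer atom indices (non-empty).
#' @param reference `"first_frame"`, or an external single-frame
#'   [trajectory()] with the same number of selected atoms (its selection
#'   taken by `ref_sel`, defaulting to all its atoms).
#' @param ref_sel Optional indices into the external reference.
#' @return Data frame with `frame`, `time_ps`, `rmsd_A`.
#' @export
rmsd_series <- function(traj, sel, reference = "first_frame", ref_sel = NULL) {
  if (length(sel) == 0) stop("selection is empty")
  xyz <- traj_to_xyz(traj, sel)
  if (identical(reference, "first_frame")) {
    ref <- xyz[1, ]
  } else if (inherits(reference, "trajectory")) {
    if (is.null(ref_sel)) ref_sel <- seq_len(n_atoms(reference))
    if (length(ref_sel) != length(sel)) {
      stop("reference selects ", length(ref_sel), " atoms but trajectory ",
           "selection has ", length(sel))
    }
    ref <- as.vector(t(frame_coords(reference, 1L)[ref_sel, , drop = FALSE]))
  } else {
    stop("reference must be \"first_frame\" or a trajectory")
  }
  inds <- seq_len(3 * length(sel))
  vals <- bio3d::rmsd(a = ref, b = xyz, fit = TRUE,
                      a.inds = inds, b.inds = inds)
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
             rmsd_A = as.numeric(vals))
}

#' Per-residue RMSF about the superposed mean structure
#'
#' Every frame is superposed onto the time-average structure, the average
#' is recomputed from the fitted frames, and the procedure is iterated
#' (two passes). RMSF is the per-atom root-mean-square deviation from the
#' final mean, reported per residue of the selection (C-alpha selections
#' give one value per residue).
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param sel Integer atom indices.
#' @param iterations Mean-structure refinement passes (default 2).
#' @return Data frame with `chain`, `resno`, `name`, `rmsf_A`.
#' @export
rmsf_profile <- function(traj, sel, iterations = 2) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  if (length(sel) == 0) stop("selection is empty")
  xyz <- traj_to_xyz(traj, sel)
  fitted <- xyz
  mref <- xyz[1, ]
  inds <- seq_len(ncol(xyz))
  for (it in seq_len(iterations)) {
    fitted <- bio3d::fit.xyz(fixed = mref, mobile = xyz,
                             fixed.inds = inds, mobile.inds = inds)
    mref <- colMeans(fitted)
  }
  dev2 <- sweep(fitted, 2, mref)^2
  # time-mean squared deviation per coordinate; sum x,y,z per atom
  per_atom <- sqrt(colSums(matrix(colMeans(dev2), nrow = 3)))
  a <- traj$atoms[sel, , drop = FALSE]
  data.frame(chain = a$chain, resno = a$resno, name = a$name,
             rmsf_A = as.numeric(per_atom), stringsAsFactors = FALSE)
}
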