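#' Rectangular fit region for the curvature patch
#'
#' The patch of phosphorus atoms used for circle fitting: a rectangle of
#' `length_x` x `width_y` ångström in the membrane (x, y) plane, centred
#' either on the dimer footprint centroid (`anchor = "dimer_footprint"`) or
#' on a fixed point (`anchor = "absolute"`, for the no-protein control).
#' Defaults mirror the 160 x 10 ångström^2 strip under the dimer's long
#' axis.
#'
#' @param length_x,width_y Patch extents in ångström (> 0).
#' @param anchor `"dimer_footprint"` or `"absolute"`.
#' @param absolute_origin Length-2 numeric (x, y) centre used when
#'   `anchor = "absolute"`.
#' @return An object of class `fit_region`.
#' @export
fit_region <- function(length_x = 160, width_y = 10,
                       anchor = c("dimer_footprint", "absolute"),
                       absolute_origin = c(0, 0)) {
  anchor <- match.arg(anchor)
  if (length_x <= 0 || width_y <= 0) stop("region extents must be positive")
  structure(list(length_x = length_x, width_y = width_y, anchor = anchor,
                 absolute_origin = absolute_origin), class = "fit_region")
}

#' Align frames to the membrane plane and dimer axis
#'
#' Rigidly transforms every frame so that (i) the best-fit plane of the
#' membrane phosphorus atoms has normal +z, with the dimer on the +z side,
#' (ii) the membrane phosphorus centroid sits at the origin, and (iii) the
#' principal (longest) axis of the dimer's atom cloud lies along x. The x
#' direction's sign is fixed deterministically: the first selected dimer
#' atom has non-negative x in frame 1, and subsequent frames keep the axis
#' continuous with the previous frame. Internal distances are unchanged.
#'
#' @param traj A [trajectory()].
#' @param membrane_sel Integer indices of the membrane phosphorus atoms.
#' @param dimer_sel Integer indices of the dimer atoms (e.g. all C-alpha).
#' @return The aligned [trajectory()].
#' @export
align_frames <- function(traj, membrane_sel, dimer_sel) {
  if (length(membrane_sel) == 0) stop("membrane selection is empty")
  if (length(dimer_sel) == 0) stop("dimer selection is empty")
  out <- traj
  prev_axis <- NULL
  for (f in seq_len(n_frames(traj))) {
    X <- frame_coords(traj, f)
    mem <- X[membrane_sel, , drop = FALSE]
    pl <- fit_plane(mem)
    nrm <- pl$normal
    dimer_ctr <- colMeans(X[dimer_sel, , drop = FALSE])
    if (sum((dimer_ctr - pl$centroid) * nrm) < 0) nrm <- -nrm
    # rotation taking nrm to +z
    v <- cross3(nrm, c(0, 0, 1))
    s <- vec_norm(v)
    cth <- nrm[3]
    R1 <- if (s < 1e-12) {
      if (cth > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      rotation_matrix(v, atan2(s, cth) * 180 / pi)
    }
    Xr <- sweep(X, 2, pl$centroid) %*% t(R1)
    # dimer long axis -> x, rotation about z only
    D <- Xr[dimer_sel, 1:2, drop = FALSE]
    Dc <- sweep(D, 2, colMeans(D))
    e <- svd(Dc, nu = 0, nv = 2)$v[, 1]
    ref <- if (is.null(prev_axis)) {
      v1 <- Xr[dimer_sel[1], 1:2] - colMeans(D)
      if (vec_norm(v1) < 1e-9) c(1, 0) else v1
    } else prev_axis
    if (sum(e * ref) < 0) e <- -e
    prev_axis <- e
    ang <- atan2(e[2], e[1]) * 180 / pi
    R2 <- rotation_matrix(c(0, 0, 1), -ang)
    out$coords[, , f] <- Xr %*% t(R2)
  }
  out
}

#' Select the phosphorus patch under the dimer for one frame
#'
#' Returns the subset of phosphorus atoms whose (x, y) position falls
#' inside the fit-region rectangle centred on the dimer footprint centroid
#' (or the absolute origin). Boundaries are inclusive with a 1e-9 ångström
#' tolerance. Fewer than 3 atoms in the patch is a fit-infeasible signal:
#' the frame is meant to be flagged, not fatal, so the (short) index vector
#' is returned and the caller decides.
#'
#' @param traj An aligned [trajectory()].
#' @param frame Frame index.
#' @param phosphorus Integer indices of candidate phosphorus atoms.
#' @param region A [fit_region()].
#' @param dimer Integer indices of dimer atoms (required for
#'   `anchor = "dimer_footprint"`).
#' @return Integer vector of patch atom indices (topology order).
#' @export
extract_patch <- function(traj, frame, phosphorus, region, dimer = NULL) {
  X <- frame_coords(traj, frame)
  centre <- if (region$anchor == "dimer_footprint") {
    if (is.null(dimer) || length(dimer) == 0) {
      stop("dimer selection required for dimer_footprint anchoring")
    }
    colMeans(X[dimer, 1:2, drop = FALSE])
  } else {
    region$absolute_origin
  }
  P <- X[phosphorus, , drop = FALSE]
  tol <- 1e-9
  keep <- abs(P[, 1] - centre[1]) <= region$length_x / 2 + tol &
    abs(P[, 2] - centre[2]) <= region$width_y / 2 + tol
  phosphorus[keep]
}

#' Per-frame membrane curvature by circle fitting
#'
#' For each frame, the phosphorus atoms inside the fit region are projected
#' to the x-z plane (the 10-ångström strip is thin in y, so the fit is
#' effectively two-dimensional) and a least-squares circle is fitted with
#' [fit_circle()]. The sign is +1 when the fitted circle's centre lies on
#' the protein side of the points (above their mean z), i.e. the membrane
#' bulges toward the protein, and -1 otherwise; flat frames get +1 by
#' convention. Frames whose patch has fewer than 3 atoms are flagged
#' infeasible and excluded from the window statistics.
#'
#' @param traj An aligned [trajectory()].
#' @param phosphorus Integer indices of membrane phosphorus atoms.
#' @param region A [fit_region()].
#' @param dimer Integer dimer indices (footprint anchoring).
#' @param window_fraction Trailing fraction of frames over which the window
#'   mean/sd of the curvature is computed (default final third, mirroring a
#'   final-100-of-300-ns average).
#' @param refine Passed to [fit_circle()].
#' @return An object of class `curvature_series`: a data frame with columns
#'   `frame`, `time_ps`, `kappa_nm`, `R_nm`, `sign`, `rms_residual`,
#'   `n_points`, `feasible`, plus attributes `window_mean`, `window_sd`,
#'   `window_frames`, `n_excluded`.
#' @export
curvature_series <- function(traj, phosphorus, region = fit_region(),
                             dimer = NULL, window_fraction = 1 / 3,
                             refine = TRUE) {
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("window_fraction must be in (0, 1]")
  }
  nf <- n_frames(traj)
  res <- data.frame(frame = seq_len(nf), time_ps = traj$times,
                    kappa_nm = NA_real_, R_nm = NA_real_, sign = NA_integer_,
                    rms_residual = NA_real_, n_points = 0L, feasible = FALSE)
  for (f in seq_len(nf)) {
    patch <- extract_patch(traj, f, phosphorus, region, dimer)
    res$n_points[f] <- length(patch)
    if (length(patch) < 3) next
    P <- frame_coords(traj, f)[patch, c(1, 3), drop = FALSE]
    fit <- fit_circle(P, refine = refine)
    res$feasible[f] <- TRUE
    res$kappa_nm[f] <- fit$kappa_nm
    res$R_nm[f] <- if (is.finite(fit$radius)) fit$radius / 10 else Inf
    res$rms_residual[f] <- fit$rms_residual
    res$sign[f] <- if (!is.finite(fit$radius) ||
                       fit$center[2] > mean(P[, 2])) 1L else -1L
  }
  if (!any(res$feasible)) stop("no frame had a feasible curvature fit")
  w0 <- nf - max(1L, ceiling(window_fraction * nf)) + 1L
  win <- res[res$frame >= w0 & res$feasible, ]
  signed <- win$kappa_nm * win$sign
  structure(res,
            window_mean = mean(signed),
            window_sd = stats::sd(signed),
            window_frames = c(w0, nf),
            n_excluded = sum(!res$feasible),
            class = c("curvature_series", "data.frame"))
}

#' Specification of the centripetal-displacement measurement
#'
#' @param center_residues Data frame with columns `chain`, `resno`, `name`
#'   giving the atoms whose mean position defines the concave-surface
#'   centre (default: GLY69 C-alpha on chains A and B).
#' @param lipid_selection An [atom_selection()] picking the tracked lipid
#'   phosphorus atoms (default: all atoms named `P`).
#' @return An object of class `displacement_spec`.
#' @export
displacement_spec <- function(center_residues = data.frame(
                                chain = c("A", "B"), resno = c(69, 69),
                                name = c("CA", "CA"),
                                stringsAsFactors = FALSE),
                              lipid_selection = atom_selection(name = "P")) {
  structure(list(center_residues = center_residues,
                 lipid_selection = lipid_selection),
            class = "displacement_spec")
}

#' Horizontal lipid displacement from the dimer centre
#'
#' For each tracked lipid phosphorus atom, the in-plane (x, y; z ignored)
#' distance to the centroid of the centre atoms (mean of the GLY69 C-alpha
#' positions of the two chains by default) is computed per frame; the
#' series is the mean over tracked lipids.
#'
#' @param traj An aligned [trajectory()].
#' @param spec A [displacement_spec()].
#' @return Data frame with `frame`, `time_ps`, `mean_distance_A`, plus a
#'   `per_lipid` attribute (frames x lipids matrix of distances).
#' @export
horizontal_displacement_series <- function(traj, spec = displacement_spec()) {
  a <- traj$atoms
  ctr_idx <- integer(0)
  for (k in seq_len(nrow(spec$center_residues))) {
    r <- spec$center_residues[k, ]
    i <- which(a$chain == r$chain & a$resno == r$resno & a$name == r$name)
    if (length(i) == 0) {
      stop("centre atom not found: chain ", r$chain, " residue ", r$resno,
           " atom ", r$name)
    }
    ctr_idx <- c(ctr_idx, i)
  }
  lip <- select_atoms(traj, spec$lipid_selection)
  if (length(lip) == 0) stop("tracked lipid selection is empty")
  nf <- n_frames(traj)
  per <- matrix(NA_real_, nf, length(lip))
  for (f in seq_len(nf)) {
    X <- frame_coords(traj, f)
    ctr <- colMeans(X[ctr_idx, , drop = FALSE])
    dx <- X[lip, 1] - ctr[1]
    dy <- X[lip, 2] - ctr[2]
    per[f, ] <- sqrt(dx^2 + dy^2)
  }
  out <- data.frame(frame = seq_len(nf), time_ps = traj$times,
                    mean_distance_A = rowMeans(per))
  attr(out, "per_lipid") <- per
  out
}
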