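#' Define an arm/core helix segment
#'
#' @param chain Chain id.
#' @param label `"arm"`, `"core"` or another label such as `"helix2"`.
#' @param residue_range Inclusive length-2 integer residue range covering
#'   at least 3 residues.
#' @param atom_name Atom used for the axis fit (default `CA`).
#' @return An object of class `segment_def`.
#' @export
segment_def <- function(chain, label, residue_range, atom_name = "CA") {
  if (diff(range(residue_range)) < 2) {
    stop("segment needs at least 3 residues for an axis fit")
  }
  structure(list(chain = chain, label = label,
                 residue_range = as.integer(range(residue_range)),
                 atom_name = atom_name), class = "segment_def")
}

#' Default arm/core segmentation of Helix 2 for both chains
#'
#' Core ARG92-VAL114 and arm VAL114-SER157 per chain; the kink residue 114
#' belongs to both ranges.
#'
#' @param arm_range,core_range Inclusive residue ranges.
#' @param chains Chain ids (length 2).
#' @return Named list of [segment_def()] objects
#'   (`arm_A`, `core_A`, `arm_B`, `core_B`).
#' @export
default_segments <- function(arm_range = c(114, 157),
                             core_range = c(92, 114),
                             chains = c("A", "B")) {
  out <- list()
  for (ch in chains) {
    out[[paste0("arm_", ch)]] <- segment_def(ch, "arm", arm_range)
    out[[paste0("core_", ch)]] <- segment_def(ch, "core", core_range)
  }
  out
}

segment_indices <- function(traj, segment) {
  a <- traj$atoms
  rr <- segment$residue_range
  idx <- which(a$chain == segment$chain & a$name == segment$atom_name &
                 a$resno >= rr[1] & a$resno <= rr[2])
  found <- a$resno[idx]
  expect <- seq(rr[1], rr[2])
  missing <- setdiff(expect, found)
  if (length(missing) > 0) {
    stop("segment ", segment$label, " chain ", segment$chain,
         ": unresolved residue(s) ", paste(missing, collapse = ", "))
  }
  idx[order(found)]
}

#' Fit the axis of a helix segment
#'
#' Principal axis (direction of maximal variance) of the segment's C-alpha
#' coordinates, oriented N- to C-terminus; `rms_perp` is the
#' root-mean-square perpendicular distance of the atoms from the axis.
#'
#' @param traj A [trajectory()].
#' @param segment A [segment_def()].
#' @param frame Frame index.
#' @return An object of class `axis_fit`: list with unit `direction`,
#'   `centroid`, `rms_perp` (ångström) and `n_atoms`.
#' @export
fit_segment_axis <- function(traj, segment, frame = 1L) {
  idx <- segment_indices(traj, segment)
  if (length(idx) < 3) stop("axis fit needs at least 3 atoms")
  X <- frame_coords(traj, frame)[idx, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  v <- svd(Xc, nu = 0, nv = 3)$v[, 1]
  if (sum(v * (X[nrow(X), ] - X[1, ])) < 0) v <- -v
  proj <- Xc %*% v
  perp2 <- rowSums(Xc^2) - proj^2
  structure(list(direction = as.vector(v), centroid = ctr,
                 rms_perp = sqrt(mean(pmax(perp2, 0))),
                 n_atoms = length(idx)),
            class = "axis_fit")
}

#' Detect helix kinks by sliding paired windows
#'
#' Two adjacent non-overlapping windows of `window` C-alpha atoms slide
#' along the helix; at each junction the bend angle is the angle between
#' the two windows' helix axes, and kinks are called at local maxima of the
#' bend angle that reach `threshold`. Window axes use the helix
#' local-normal construction (exact on ideal helices; see
#' `helix_window_axis`), so an unkinked ideal helix yields zero calls at
#' any threshold. The reported `center_residue` is the first residue of the
#' trailing window — the pivot residue for a planted rigid kink.
#'
#' @param traj A [trajectory()].
#' @param chain Chain id.
#' @param helix_range Inclusive length-2 residue range
#'   (length >= `2 * window`).
#' @param window Window length in residues (>= 4; default 6).
#' @param threshold Calling threshold in degrees (default 20).
#' @param frame Frame index.
#' @return Data frame of class `kink_calls` with columns `chain`,
#'   `window_start`, `window_end`, `center_residue`, `bend_angle`; the full
#'   bend-angle profile is attached as attribute `profile`.
#' @export
detect_kinks <- function(traj, chain, helix_range, window = 6,
                         threshold = 20, frame = 1L) {
  if (window < 4) stop("window must be >= 4 residues")
  rr <- range(helix_range)
  if (diff(rr) + 1 < 2 * window) {
    stop("helix_range spans ", diff(rr) + 1,
         " residues; need at least 2 * window = ", 2 * window)
  }
  seg <- segment_def(chain, "helix", rr)
  idx <- segment_indices(traj, seg)
  X <- frame_coords(traj, frame)[idx, , drop = FALSE]
  resno <- seq(rr[1], rr[2])
  n <- length(resno)
  centers <- seq(window + 1L, n - window + 1L)
  prof <- vapply(centers, function(j) {
    ax1 <- helix_window_axis(X[(j - window):(j - 1), , drop = FALSE])
    ax2 <- helix_window_axis(X[j:(j + window - 1), , drop = FALSE])
    c(angle_between(ax1, ax2),
      min(attr(ax1, "consistency"), attr(ax2, "consistency")))
  }, numeric(2))
  bend <- prof[1, ]
  qual <- prof[2, ]
  profile <- data.frame(center_residue = resno[centers], bend_angle = bend,
                        window_consistency = qual)
  is_max <- bend >= threshold &
    bend >= c(-Inf, bend[-length(bend)]) &
    bend > c(bend[-1], -Inf)
  # Re-centre each raw maximum on window consistency: windows straddling a
  # rigid kink are not ideal helices and their axes can slightly overshoot
  # the true bend, displacing the raw maximum by a residue or two. The
  # junction whose two flanking windows are the most perfectly helical
  # (highest consistency) localises the kink; ties go to the larger bend,
  # then the smaller residue number (the pivot of a planted rotation).
  picked <- integer(0)
  for (m in which(is_max)) {
    nb <- seq(max(1L, m - (window - 2L)), min(length(bend), m + (window - 2L)))
    nb <- nb[bend[nb] >= threshold]
    qmax <- max(qual[nb])
    cand <- nb[qual[nb] >= qmax - 1e-9]
    bmax <- max(bend[cand])
    cand <- cand[bend[cand] >= bmax - 1e-9]
    picked <- c(picked, cand[1])
  }
  picked <- unique(picked)
  calls <- data.frame(chain = rep(chain, length(picked)),
                      window_start = resno[centers[picked] - window],
                      window_end = resno[pmin(centers[picked] + window - 1L,
                                              n)],
                      center_residue = resno[centers[picked]],
                      bend_angle = bend[picked],
                      stringsAsFactors = FALSE)
  structure(calls, profile = profile, window = window,
            threshold = threshold, class = c("kink_calls", "data.frame"))
}

#' Per-frame inter-chain angles and dimer span
#'
#' For every frame: `alpha` is the angle between the two chains' arm
#' segment axes, `beta` between the core axes, `gamma` between the whole
#' Helix-2 axes (union of core and arm ranges), and `d` the distance
#' between the two span-anchor atoms (SER157 C-alpha of chains A and B by
#' default). Axes are principal axes oriented N to C; angles are folded to
#' [0, 180] degrees. Frames where any axis fit fails are flagged, excluded,
#' and counted in the `n_excluded` attribute.
#'
#' @param traj A [trajectory()].
#' @param segments Named list from [default_segments()] (needs `arm_A`,
#'   `core_A`, `arm_B`, `core_B`).
#' @param span_anchor Data frame with two rows and columns `chain`,
#'   `resno`, `name` giving the span anchor atoms.
#' @return Data frame of class `angle_span_series` with columns `frame`,
#'   `time_ps`, `alpha_deg`, `beta_deg`, `gamma_deg`, `d_A`, `ok`.
#' @export
angle_span_series <- function(traj, segments = default_segments(),
                              span_anchor = data.frame(
                                chain = c("A", "B"), resno = c(157, 157),
                                name = c("CA", "CA"),
                                stringsAsFactors = FALSE)) {
  need <- c("arm_A", "core_A", "arm_B", "core_B")
  if (!all(need %in% names(segments))) {
    stop("segments must contain ", paste(need, collapse = ", "))
  }
  h2 <- lapply(c(A = "A", B = "B"), function(ch) {
    segment_def(ch, "helix2",
                range(c(segments[[paste0("core_", ch)]]$residue_range,
                        segments[[paste0("arm_", ch)]]$residue_range)))
  })
  a <- traj$atoms
  anchor_idx <- vapply(1:2, function(k) {
    r <- span_anchor[k, ]
    i <- which(a$chain == r$chain & a$resno == r$resno & a$name == r$name)
    if (length(i) != 1) {
      stop("span anchor not resolved: chain ", r$chain, " residue ", r$resno,
           " atom ", r$name)
    }
    i
  }, integer(1))

  nf <- n_frames(traj)
  out <- data.frame(frame = seq_len(nf), time_ps = traj$times,
                    alpha_deg = NA_real_, beta_deg = NA_real_,
                    gamma_deg = NA_real_, d_A = NA_real_, ok = FALSE)
  for (f in seq_len(nf)) {
    res <- tryCatch({
      armA <- fit_segment_axis(traj, segments$arm_A, f)$direction
      armB <- fit_segment_axis(traj, segments$arm_B, f)$direction
      corA <- fit_segment_axis(traj, segments$core_A, f)$direction
      corB <- fit_segment_axis(traj, segments$core_B, f)$direction
      h2A <- fit_segment_axis(traj, h2$A, f)$direction
      h2B <- fit_segment_axis(traj, h2$B, f)$direction
      X <- frame_coords(traj, f)
      c(angle_between(armA, armB), angle_between(corA, corB),
        angle_between(h2A, h2B),
        vec_norm(X[anchor_idx[1], ] - X[anchor_idx[2], ]))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$alpha_deg[f] <- res[1]
      out$beta_deg[f] <- res[2]
      out$gamma_deg[f] <- res[3]
      out$d_A[f] <- res[4]
      out$ok[f] <- TRUE
    }
  }
  structure(out, n_excluded = sum(!out$ok),
            provenance = list(arm = segments$arm_A$residue_range,
                              core = segments$core_A$residue_range,
                              helix2 = h2$A$residue_range,
                              span_anchor = span_anchor),
            class = c("angle_span_series", "data.frame"))
}

#' Pearson product-moment correlation with degeneracy signalling
#'
#' Sample Pearson correlation of two equal-length series. A constant series
#' makes the coefficient undefined; this is reported as `NA` with a
#' warning, never silently coerced to 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or `NA` when undefined.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for a constant series; reported as NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Correlation table over the angle/span series
#'
#' @param series An [angle_span_series()] (or a list of them, pooled or
#'   averaged per trajectory according to `pooling`).
#' @param pairs List of length-2 character vectors naming series among
#'   `alpha`, `beta`, `gamma`, `d`.
#' @param pooling `"pooled"` (concatenate frames across trajectories before
#'   correlating) or `"per_trajectory"` (correlate each trajectory, then
#'   average the coefficients).
#' @return Data frame with columns `x`, `y`, `r` and attribute `pooling`.
#' @export
correlation_summary <- function(series,
                                pairs = list(c("alpha", "d"), c("beta", "d"),
                                             c("gamma", "d"),
                                             c("alpha", "beta")),
                                pooling = c("pooled", "per_trajectory")) {
  pooling <- match.arg(pooling)
  if (inherits(series, "angle_span_series")) series <- list(series)
  cols <- c(alpha = "alpha_deg", beta = "beta_deg", gamma = "gamma_deg",
            d = "d_A")
  get <- function(s, nm) {
    if (!nm %in% names(cols)) stop("unknown series name: ", nm)
    s[s$ok, cols[nm]]
  }
  r <- vapply(pairs, function(p) {
    if (pooling == "pooled") {
      x <- unlist(lapply(series, get, p[1]))
      y <- unlist(lapply(series, get, p[2]))
      pearson_cor(x, y)
    } else {
      mean(vapply(series, function(s) pearson_cor(get(s, p[1]),
                                                  get(s, p[2])),
                  numeric(1)))
    }
  }, numeric(1))
  out <- data.frame(x = vapply(pairs, `[`, character(1), 1),
                    y = vapply(pairs, `[`, character(1), 2), r = r,
                    stringsAsFactors = FALSE)
  attr(out, "pooling") <- pooling
  out
}
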