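#' Specification for a synthetic kinked pseudo-dimer
#'
#' Each chain is an ideal-helix C-alpha trace (rise 1.5 ångström/residue,
#' 100 degrees/residue twist, helix radius 2.3 ångström) whose axis lies
#' along x, kinked at a central residue. The part C-terminal of the kink —
#' containing the "arm segment" — is rigidly rotated about the kink C-alpha
#' so the arm tip lifts out of the membrane plane by the static
#' `kink_angle` plus a per-frame swing; the part N-terminal of the kink can
#' rock independently (the "core" channel). Chain B is the C2 rotation of
#' chain A about z (180 degrees), which preserves helix chirality and gives
#' the dimer its two-fold symmetry. Residue numbering runs
#' `first_residue:last_residue` as in the construct the defaults mirror
#' (221 residues, 19–239; kink VAL114; core ARG92–VAL114; arm
#' VAL114–SER157; span anchor SER157).
#'
#' @param first_residue,last_residue Inclusive residue numbering per chain.
#' @param kink_residue Kink residue; must lie strictly inside the chain and
#'   be the single shared residue of `core_range` and `arm_range`.
#' @param arm_range,core_range Inclusive residue ranges (length-2 integer).
#' @param helix_rise Rise per residue along the axis, ångström.
#' @param helix_radius Helical C-alpha radius, ångström.
#' @param helix_twist Twist per residue, degrees.
#' @param kink_angle Static arm lift at the kink, degrees.
#' @param gap Inter-chain gap at the dimer centre along x, ångström.
#' @param z_offset Rigid z translation of the whole dimer, ångström.
#' @param arm_angle_series Optional explicit per-frame arm swing theta(t) in
#'   degrees: a vector (both chains) or an `n_frames x 2` matrix (chain A,
#'   chain B). Overrides the motion process.
#' @param noise_sd Isotropic positional noise sd, ångström (default 0).
#' @param seed Integer RNG seed.
#' @return An object of class `dimer_spec`.
#' @export
dimer_spec <- function(first_residue = 19, last_residue = 239,
                       kink_residue = 114, arm_range = c(114, 157),
                       core_range = c(92, 114), helix_rise = 1.5,
                       helix_radius = 2.3, helix_twist = 100,
                       kink_angle = 20, gap = 4, z_offset = 0,
                       arm_angle_series = NULL, noise_sd = 0, seed = 1) {
  if (kink_residue <= first_residue || kink_residue >= last_residue) {
    stop("kink_residue must lie strictly inside the chain")
  }
  shared <- intersect(seq(core_range[1], core_range[2]),
                      seq(arm_range[1], arm_range[2]))
  if (!identical(shared, as.integer(kink_residue)) &&
      !identical(shared, kink_residue)) {
    stop("arm and core ranges must share exactly the kink residue")
  }
  structure(list(first_residue = as.integer(first_residue),
                 last_residue = as.integer(last_residue),
                 kink_residue = as.integer(kink_residue),
                 arm_range = as.integer(arm_range),
                 core_range = as.integer(core_range),
                 helix_rise = helix_rise, helix_radius = helix_radius,
                 helix_twist = helix_twist, kink_angle = kink_angle,
                 gap = gap, z_offset = z_offset,
                 arm_angle_series = arm_angle_series,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dimer_spec")
}

#' Specification of the arm-swing dynamics
#'
#' The default stochastic process is a discrete Ornstein-Uhlenbeck (mean
#' reverting) swing shared by the two arms, with stationary standard
#' deviation `amplitude` and relaxation time `relaxation_frames`. When
#' `correlation_alpha_d` is set, an independent OU "span breathing" term
#' (rigid +/- x translation of the chains) is added whose sd is computed in
#' closed form from the anchor kinematics so that the planted
#' Pearson(alpha, d) equals the target; an independent OU core-rocking
#' channel of sd `core_amplitude` drives beta without touching alpha or d.
#'
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame spacing, ps.
#' @param process `"ou"`, `"sinusoid"` or `"constant"` (theta = 0).
#' @param amplitude Swing scale in degrees (OU stationary sd, or sinusoid
#'   amplitude).
#' @param correlation_alpha_d Optional target Pearson correlation between
#'   the arm angle alpha and the span d, in (0, 1]. The construction
#'   geometry makes alpha and d co-move positively, so only non-negative
#'   targets are supported.
#' @param core_amplitude Stationary sd of the independent core-rocking
#'   channel, degrees (0 disables it).
#' @param relaxation_frames OU relaxation time in frames.
#' @param period Sinusoid period in frames.
#' @param seed Integer RNG seed.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(n_frames = 100, dt = 100, process = c("ou", "sinusoid",
                                                              "constant"),
                        amplitude = 5, correlation_alpha_d = NULL,
                        core_amplitude = 2, relaxation_frames = 10,
                        period = 50, seed = 1) {
  process <- match.arg(process)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (!is.null(correlation_alpha_d)) {
    if (correlation_alpha_d <= 0 || correlation_alpha_d > 1) {
      stop("correlation_alpha_d must be in (0, 1]: the construction geometry",
           " couples alpha and d positively")
    }
  }
  structure(list(n_frames = as.integer(n_frames), dt = dt, process = process,
                 amplitude = amplitude,
                 correlation_alpha_d = correlation_alpha_d,
                 core_amplitude = core_amplitude,
                 relaxation_frames = relaxation_frames, period = period,
                 seed = as.integer(seed)),
            class = "motion_spec")
}

# Discrete stationary OU path with sd sigma and relaxation tau (frames).
ou_path <- function(n, sigma, tau) {
  if (sigma == 0) return(rep(0, n))
  phi <- exp(-1 / tau)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, sd = sigma)
  innov <- stats::rnorm(n - 1, sd = sigma * sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

# Residue names planted at positions that matter downstream; ALA elsewhere.
dimer_resnames <- function(resno) {
  named <- c("19" = "ARG", "23" = "LYS", "47" = "LYS", "48" = "ARG",
             "69" = "GLY", "92" = "ARG", "114" = "VAL", "128" = "PHE",
             "132" = "LYS", "157" = "SER", "194" = "LEU")
  out <- rep("ALA", length(resno))
  hit <- match(as.character(resno), names(named))
  out[!is.na(hit)] <- named[hit[!is.na(hit)]]
  out
}

#' Generate a kinked, arm-swinging pseudo-dimer trajectory with ground truth
#'
#' Ground-truth quantities are computed from the same affine construction
#' that emits the coordinates (rotated ideal axis vectors and axis points),
#' independent of the estimators under test: `alpha_true` is the angle
#' between the two rotated arm axis directions, `beta_true` between the two
#' core axis directions, `gamma_true` between the two Helix-2 axis chords
#' (axis point at the last Helix-2 residue minus axis point at the first),
#' and `d_true` the distance between the two span-anchor C-alpha atoms.
#'
#' @param spec A [dimer_spec()].
#' @param motion A [motion_spec()]; ignored when `spec$arm_angle_series`
#'   is supplied (then the swing is exactly the given series and the core
#'   and breathing channels are zero).
#' @return List with `trajectory` (chains `A`, `B`; C-alpha atoms only) and
#'   `truth` (data frame with `time_ps`, `alpha_true`, `beta_true`,
#'   `gamma_true`, `d_true`, `theta_A`, `theta_B`, `eps_A`, `eps_B`,
#'   `breathing_w`).
#' @export
generate_dimer_trajectory <- function(spec, motion = motion_spec()) {
  stopifnot(inherits(spec, "dimer_spec"))
  resno <- seq(spec$first_residue, spec$last_residue)
  nres <- length(resno)
  idx0 <- resno - spec$first_residue
  s_ax <- idx0 * spec$helix_rise
  phase <- idx0 * spec$helix_twist * pi / 180
  x_start <- spec$gap / 2

  # unrotated chain-A helix and its on-axis polyline
  base <- cbind(x_start + s_ax,
                spec$helix_radius * cos(phase),
                spec$helix_radius * sin(phase))
  base_axis <- cbind(x_start + s_ax, 0, 0)
  k_i <- match(spec$kink_residue, resno)
  pivot <- base[k_i, ]
  arm_i <- which(resno >= spec$kink_residue)
  core_i <- which(resno < spec$kink_residue)

  # per-frame angles
  if (!is.null(spec$arm_angle_series)) {
    th <- spec$arm_angle_series
    if (is.null(dim(th))) th <- cbind(th, th)
    nf <- nrow(th)
    eps <- matrix(0, nf, 2)
    w <- rep(0, nf)
    dt <- if (inherits(motion, "motion_spec")) motion$dt else 1
    set.seed(spec$seed)
  } else {
    stopifnot(inherits(motion, "motion_spec"))
    nf <- motion$n_frames
    dt <- motion$dt
    set.seed(motion$seed)
    shared <- switch(motion$process,
                     ou = ou_path(nf, motion$amplitude,
                                  motion$relaxation_frames),
                     sinusoid = motion$amplitude *
                       sin(2 * pi * (seq_len(nf) - 1) / motion$period),
                     constant = rep(0, nf))
    th <- cbind(shared, shared)
    eps <- cbind(ou_path(nf, motion$core_amplitude, motion$relaxation_frames),
                 ou_path(nf, motion$core_amplitude, motion$relaxation_frames))
    w <- rep(0, nf)
    if (!is.null(motion$correlation_alpha_d) && motion$amplitude > 0) {
      # closed-form span slope wrt the shared swing at the working point:
      # anchor x(phi) = pivot_x + v1 cos(phi) + v3 sin(phi) under the lift
      # rotation, so dx/dphi = -v1 sin(phi0) + v3 cos(phi0) per radian and
      # d(d)/ds = 2 * dx/dphi (both chains share s). The breathing sd that
      # yields Pearson(alpha, d) = rho is |d(d)/ds| * sd(s) * sqrt(1/rho^2-1).
      a_i <- match(spec$arm_range[2], resno)
      v <- base[a_i, ] - pivot
      phi0 <- spec$kink_angle * pi / 180
      dx_dphi <- -v[1] * sin(phi0) + v[3] * cos(phi0)
      slope <- 2 * abs(dx_dphi) * pi / 180      # angstrom per degree of s
      rho <- motion$correlation_alpha_d
      sd_w <- slope * motion$amplitude * sqrt(1 / rho^2 - 1)
      w <- ou_path(nf, sd_w, motion$relaxation_frames)
    }
  }

  lift <- function(angle_deg) rotation_matrix(c(0, 1, 0), -angle_deg)
  c2 <- rotation_matrix(c(0, 0, 1), 180)

  # one chain in the chain-A frame; returns coords and ground-truth pieces
  build_chain <- function(theta, epsilon) {
    phi_arm <- spec$kink_angle + theta
    A <- lift(phi_arm)
    C <- lift(-epsilon)
    X <- base
    Xax <- base_axis
    X[arm_i, ] <- sweep(sweep(X[arm_i, , drop = FALSE], 2, pivot) %*% t(A),
                        2, pivot, `+`)
    Xax[arm_i, ] <- sweep(sweep(Xax[arm_i, , drop = FALSE], 2, pivot) %*% t(A),
                          2, pivot, `+`)
    if (length(core_i) > 0) {
      X[core_i, ] <- sweep(sweep(X[core_i, , drop = FALSE], 2, pivot) %*% t(C),
                           2, pivot, `+`)
      Xax[core_i, ] <- sweep(sweep(Xax[core_i, , drop = FALSE], 2, pivot) %*%
                               t(C), 2, pivot, `+`)
    }
    list(X = X, Xax = Xax,
         u_arm = as.vector(A %*% c(1, 0, 0)),
         u_core = as.vector(C %*% c(1, 0, 0)))
  }

  h2_lo <- match(min(spec$core_range), resno)
  h2_hi <- match(max(spec$arm_range), resno)
  anchor_i <- match(spec$arm_range[2], resno)

  coords <- array(0, dim = c(2 * nres, 3L, nf))
  truth <- data.frame(time_ps = (seq_len(nf) - 1) * dt,
                      alpha_true = NA_real_, beta_true = NA_real_,
                      gamma_true = NA_real_, d_true = NA_real_,
                      theta_A = th[, 1], theta_B = th[, 2],
                      eps_A = eps[, 1], eps_B = eps[, 2], breathing_w = w)
  for (f in seq_len(nf)) {
    cha <- build_chain(th[f, 1], eps[f, 1])
    chb <- build_chain(th[f, 2], eps[f, 2])
    XA <- sweep(cha$X, 2, c(w[f] / 2, 0, spec$z_offset), `+`)
    XB <- sweep(chb$X %*% t(c2), 2, c(-w[f] / 2, 0, spec$z_offset), `+`)
    if (spec$noise_sd > 0) {
      XA <- XA + matrix(stats::rnorm(3 * nres, sd = spec$noise_sd), nres, 3)
      XB <- XB + matrix(stats::rnorm(3 * nres, sd = spec$noise_sd), nres, 3)
    }
    coords[seq_len(nres), , f] <- XA
    coords[nres + seq_len(nres), , f] <- XB
    truth$alpha_true[f] <- angle_between(cha$u_arm, as.vector(c2 %*% chb$u_arm))
    truth$beta_true[f] <- angle_between(cha$u_core,
                                        as.vector(c2 %*% chb$u_core))
    chordA <- cha$Xax[h2_hi, ] - cha$Xax[h2_lo, ]
    chordB <- as.vector(c2 %*% (chb$Xax[h2_hi, ] - chb$Xax[h2_lo, ]))
    truth$gamma_true[f] <- angle_between(chordA, chordB)
    truth$d_true[f] <- vec_norm(XA[anchor_i, ] - XB[anchor_i, ])
  }

  # self-intersection guard on the most-bent frame
  worst <- which.max(abs(spec$kink_angle + th[, 1]))
  Xw <- coords[seq_len(nres), , worst]
  far_arm <- arm_i[resno[arm_i] > spec$kink_residue + 2]
  far_core <- core_i[resno[core_i] < spec$kink_residue - 2]
  if (length(far_arm) > 0 && length(far_core) > 0) {
    dmin <- min(as.matrix(stats::dist(Xw[c(far_core, far_arm), ]))[
      seq_along(far_core), length(far_core) + seq_along(far_arm)])
    if (dmin < 1) {
      stop("arm rotation folds the chain onto itself (closest contact ",
           round(dmin, 2), " angstrom < 1)")
    }
  }

  atoms <- data.frame(serial = seq_len(2 * nres), name = "CA", element = "C",
                      resname = c(dimer_resnames(resno), dimer_resnames(resno)),
                      resno = c(resno, resno),
                      chain = rep(c("A", "B"), each = nres),
                      stringsAsFactors = FALSE)
  list(trajectory = trajectory(atoms, coords, truth$time_ps), truth = truth)
}

#' Generate a single kinked helix fixture
#'
#' One chain of ideal-helix C-alpha atoms with zero or more planted kinks,
#' used as ground truth for kink detection: atoms C-terminal of each kink
#' residue are rigidly rotated about that residue's C-alpha (rotation axis
#' y, applied N to C), so the bend angle between the flanking helix axes at
#' each kink equals the planted angle exactly.
#'
#' @param first_residue,last_residue Inclusive residue numbering.
#' @param kinks Data frame (or NULL) with columns `residue`, `angle_deg`.
#' @param helix_rise,helix_radius,helix_twist Ideal helix parameters.
#' @param noise_sd Isotropic positional noise sd, ångström.
#' @param seed Integer RNG seed.
#' @return A single-frame [trajectory()], chain `A`.
#' @export
generate_kinked_helix <- function(first_residue = 90, last_residue = 150,
                                  kinks = NULL, helix_rise = 1.5,
                                  helix_radius = 2.3, helix_twist = 100,
                                  noise_sd = 0, seed = 1) {
  resno <- seq(first_residue, last_residue)
  idx0 <- resno - first_residue
  phase <- idx0 * helix_twist * pi / 180
  X <- cbind(idx0 * helix_rise, helix_radius * cos(phase),
             helix_radius * sin(phase))
  if (!is.null(kinks) && nrow(kinks) > 0) {
    kinks <- kinks[order(kinks$residue), , drop = FALSE]
    for (k in seq_len(nrow(kinks))) {
      ki <- match(kinks$residue[k], resno)
      if (is.na(ki)) stop("kink residue ", kinks$residue[k], " not in chain")
      R <- rotation_matrix(c(0, 1, 0), -kinks$angle_deg[k])
      piv <- X[ki, ]
      sel <- ki:length(resno)
      X[sel, ] <- sweep(sweep(X[sel, , drop = FALSE], 2, piv) %*% t(R),
                        2, piv, `+`)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X), 3)
  }
  atoms <- data.frame(serial = seq_along(resno), name = "CA", element = "C",
                      resname = dimer_resnames(resno), resno = resno,
                      chain = "A", stringsAsFactors = FALSE)
  trajectory(atoms, X, times = 0)
}
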