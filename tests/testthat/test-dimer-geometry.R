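test_that("segment axis fits recover helix axes and respect rotation", {
  h <- generate_kinked_helix(90, 150)
  ax <- fit_segment_axis(h, segment_def("A", "core", c(92, 148)))
  expect_lt(angle_between(ax$direction, c(1, 0, 0)), 1)
  expect_equal(ax$rms_perp, 2.3, tolerance = 0.05)  # helix radius

  # 3 collinear points: axis along the line, rms_perp 0
  atoms <- data.frame(serial = 1:3, name = "CA", element = "C",
                      resname = "ALA", resno = 1:3, chain = "A")
  tr <- trajectory(atoms, cbind(c(1, 2, 3), c(2, 4, 6), c(0, 0, 0)))
  ax2 <- fit_segment_axis(tr, segment_def("A", "seg", c(1, 3)))
  expect_equal(abs(sum(ax2$direction * unit(c(1, 2, 0)))), 1,
               tolerance = 1e-9)
  expect_equal(ax2$rms_perp, 0, tolerance = 1e-9)

  # equivariance: rotated copy gives the rotated axis
  R <- rotation_matrix(c(2, -1, 1), 63)
  hr <- h
  hr$coords[, , 1] <- frame_coords(h) %*% t(R)
  axr <- fit_segment_axis(hr, segment_def("A", "core", c(92, 148)))
  expect_equal(axr$direction, as.vector(R %*% ax$direction),
               tolerance = 1e-6)
})

test_that("unresolved segment residues are named in the error", {
  h <- generate_kinked_helix(90, 150)
  expect_error(fit_segment_axis(h, segment_def("A", "arm", c(140, 160))),
               "unresolved residue")
  expect_error(fit_segment_axis(h, segment_def("B", "arm", c(92, 100))),
               "unresolved")
})

test_that("PCA axes are accurate for long segments but unusable for short windows", {
  # the reason kink windows use the local-normal axis, not PCA
  pca_tilt <- function(n) {
    h <- generate_kinked_helix(1, n)
    X <- frame_coords(h)
    v <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 3)$v[, 1]
    acos(min(1, abs(v[1]))) * 180 / pi
  }
  expect_lt(pca_tilt(44), 0.5)   # arm-segment length: sub-degree
  expect_gt(pca_tilt(6), 10)     # kink-window length: badly biased
  # the local-normal axis is exact at kink-window length
  h6 <- generate_kinked_helix(1, 6)
  ax <- helix_window_axis(frame_coords(h6))
  expect_lt(angle_between(ax, c(1, 0, 0)), 1e-6)
})

test_that("ideal helices produce no kink calls for any window", {
  h <- generate_kinked_helix(90, 150)
  for (w in 5:7) {
    expect_equal(nrow(detect_kinks(h, "A", c(92, 148), window = w)), 0)
  }
})

test_that("a planted 40 degree kink at 114 is recovered", {
  h <- generate_kinked_helix(90, 150,
                             kinks = data.frame(residue = 114,
                                                angle_deg = 40))
  calls <- detect_kinks(h, "A", c(92, 148))
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$center_residue - 114), 1)
  expect_lt(abs(calls$bend_angle - 40), 3)
})

test_that("two planted kinks 14 residues apart are both recovered", {
  h <- generate_kinked_helix(90, 150,
                             kinks = data.frame(residue = c(114, 128),
                                                angle_deg = c(40, 30)))
  calls <- detect_kinks(h, "A", c(92, 148))
  expect_equal(nrow(calls), 2)
  expect_lte(abs(calls$center_residue[1] - 114), 1)
  expect_lte(abs(calls$center_residue[2] - 128), 1)
  expect_lt(abs(calls$bend_angle[1] - 40), 3)
  expect_lt(abs(calls$bend_angle[2] - 30), 3)
})

test_that("too-short helix ranges are a precondition error", {
  h <- generate_kinked_helix(90, 150)
  expect_error(detect_kinks(h, "A", c(92, 102), window = 6), "2 \\* window")
})

test_that("angle/span series matches ground truth across the swing grid", {
  for (th in seq(0, 30, by = 5)) {
    g <- generate_dimer_trajectory(dimer_spec(arm_angle_series = th))
    s <- angle_span_series(g$trajectory)
    expect_lt(abs(s$alpha_deg[1] - g$truth$alpha_true[1]), 2)
    expect_equal(s$d_A[1], g$truth$d_true[1], tolerance = 1e-9)
  }
})

test_that("series are invariant under global rigid motion", {
  g <- generate_dimer_trajectory(dimer_spec(seed = 6),
                                 motion_spec(n_frames = 5, amplitude = 6,
                                             seed = 6))
  s0 <- angle_span_series(g$trajectory)
  withr::local_seed(33)
  moved <- apply_rigid_traj(g$trajectory, random_rigid())
  s1 <- angle_span_series(moved)
  for (col in c("alpha_deg", "beta_deg", "gamma_deg", "d_A")) {
    expect_equal(s1[[col]], s0[[col]], tolerance = 1e-6)
  }
  # rmsd/rmsf too: same motion applied to every frame cancels
  sel <- select_atoms(g$trajectory, chain = "A", name = "CA")
  expect_equal(rmsd_series(moved, sel)$rmsd_A,
               rmsd_series(g$trajectory, sel)$rmsd_A, tolerance = 1e-6)
  expect_equal(rmsf_profile(moved, sel)$rmsf_A,
               rmsf_profile(g$trajectory, sel)$rmsf_A, tolerance = 1e-6)
})

test_that("static dimers give constant estimated series", {
  g <- generate_dimer_trajectory(dimer_spec(arm_angle_series = rep(0, 4)))
  s <- angle_span_series(g$trajectory)
  expect_equal(diff(range(s$alpha_deg)), 0, tolerance = 1e-9)
  expect_equal(diff(range(s$gamma_deg)), 0, tolerance = 1e-9)
  expect_equal(diff(range(s$d_A)), 0, tolerance = 1e-9)
})

test_that("pearson matches the definitional two-pass formula", {
  expect_equal(pearson_cor(1:10, 1:10), 1)
  expect_equal(pearson_cor(1:10, -2 * (1:10) + 5), -1)
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_cor(x, y), pearson_definitional(x, y),
               tolerance = 1e-12)
  expect_equal(pearson_cor(x, y), 0.822, tolerance = 1e-3)
  withr::local_seed(77)
  for (i in 1:10) {
    a <- stats::rnorm(50)
    b <- stats::rnorm(50)
    expect_equal(pearson_cor(a, b), pearson_definitional(a, b),
                 tolerance = 1e-12)
  }
})

test_that("constant series yield an undefined-correlation signal", {
  expect_warning(r <- pearson_cor(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(r))
  expect_error(pearson_cor(1:4, 1:5), "lengths differ")
})

test_that("correlation summary reports requested pairs and pooling", {
  g <- generate_dimer_trajectory(dimer_spec(seed = 2),
                                 motion_spec(n_frames = 50, amplitude = 5,
                                             seed = 2))
  s <- angle_span_series(g$trajectory)
  ct <- correlation_summary(s, pairs = list(c("d", "d"), c("alpha", "d")))
  expect_equal(ct$r[1], 1, tolerance = 1e-12)
  expect_identical(attr(ct, "pooling"), "pooled")
  ct2 <- correlation_summary(list(s, s), pairs = list(c("alpha", "d")),
                             pooling = "per_trajectory")
  expect_equal(ct2$r, ct$r[2], tolerance = 1e-9)
})

test_that("rmsd is zero for identical or rigidly rotated frames", {
  g <- generate_dimer_trajectory(dimer_spec(arm_angle_series = rep(0, 3)))
  sel <- select_atoms(g$trajectory, name = "CA")
  expect_equal(rmsd_series(g$trajectory, sel)$rmsd_A, rep(0, 3),
               tolerance = 1e-6)
  tr <- g$trajectory
  R <- rotation_matrix(c(1, 1, 0), 45)
  tr$coords[, , 2] <- frame_coords(tr, 2) %*% t(R) + 3
  expect_equal(rmsd_series(tr, sel)$rmsd_A[2], 0, tolerance = 1e-6)
})

test_that("rmsd recovers planted isotropic displacement noise", {
  withr::local_seed(19)
  g <- generate_dimer_trajectory(dimer_spec(arm_angle_series = rep(0, 2)))
  tr <- g$trajectory
  n <- n_atoms(tr)
  # per-atom isotropic noise with 1 A RMS total displacement
  tr$coords[, , 2] <- tr$coords[, , 2] +
    matrix(stats::rnorm(3 * n, sd = 1 / sqrt(3)), n, 3)
  r <- rmsd_series(tr, seq_len(n))$rmsd_A[2]
  expect_lt(abs(r - 1), 0.1)
})

test_that("rmsf separates a jittered residue from static ones", {
  withr::local_seed(42)
  base <- generate_kinked_helix(1, 40)
  nf <- 400
  X <- array(rep(base$coords[, , 1], nf), dim = c(40, 3, nf))
  X[20, , ] <- X[20, , ] + matrix(stats::rnorm(3 * nf, sd = 2), 3, nf)
  tr <- trajectory(base$atoms, X)
  rf <- rmsf_profile(tr, 1:40)
  expect_lt(abs(rf$rmsf_A[20] - 2 * sqrt(3)) / (2 * sqrt(3)), 0.08)
  expect_lt(max(rf$rmsf_A[-20]), 0.3)
  # rigid drift only: all fluctuations vanish after superposition
  Xd <- array(rep(base$coords[, , 1], 5), dim = c(40, 3, 5))
  for (f in 1:5) Xd[, 1, f] <- Xd[, 1, f] + 3 * f
  trd <- trajectory(base$atoms, Xd)
  expect_lt(max(rmsf_profile(trd, 1:40)$rmsf_A), 1e-6)
  expect_error(rmsf_profile(trajectory(base$atoms, base$coords), 1:40),
               "at least 2 frames")
})
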