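test_that("an already-aligned flat bundle passes through alignment unchanged", {
  mem <- generate_membrane_trajectory(membrane_spec(
    radius_series = rep(Inf, 3)))
  # helix_radius 0: a straight-line dimer whose principal axis is exactly x
  dm <- generate_dimer_trajectory(dimer_spec(z_offset = 15, helix_radius = 0,
                                             kink_angle = 0,
                                             arm_angle_series = rep(0, 3)))
  b <- bind_trajectories(dm$trajectory, mem$trajectory)
  al <- align_frames(b, select_atoms(b, name = "P"),
                     select_atoms(b, name = "CA"))
  expect_equal(al$coords, b$coords, tolerance = 1e-6)
})

test_that("alignment inverts a rigid motion and preserves distances", {
  b <- make_bundle(n_frames = 3)
  mem <- select_atoms(b$traj, name = "P")
  dim_sel <- select_atoms(b$traj, name = "CA")
  ref <- align_frames(b$traj, mem, dim_sel)
  rot <- list(R = rotation_matrix(c(1, 0, 0), 90), t = c(5, -3, 12))
  moved <- apply_rigid_traj(b$traj, rot)
  back <- align_frames(moved, mem, dim_sel)
  expect_equal(back$coords, ref$coords, tolerance = 1e-6)
  # rigidity: pairwise distances unchanged by alignment
  d0 <- stats::dist(frame_coords(moved, 2)[c(1, 50, 200, 500), ])
  d1 <- stats::dist(frame_coords(back, 2)[c(1, 50, 200, 500), ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("degenerate membranes cannot be aligned", {
  line <- cbind(1:10, 0, 0)
  atoms <- data.frame(serial = 1:10, name = "P", element = "P",
                      resname = "POP", resno = 1:10, chain = "M")
  tr <- trajectory(atoms, line)
  expect_error(align_frames(tr, 1:10, 1:10), "collinear")
})

test_that("the default patch on the flat default lattice holds 42 atoms", {
  gm <- generate_membrane_trajectory(membrane_spec(radius_series = Inf))
  P <- select_atoms(gm$trajectory, name = "P")
  patch <- extract_patch(gm$trajectory, 1, P, fit_region(anchor = "absolute"))
  expect_length(patch, 42)  # 21 columns x 2 rows inside 160 x 10
  # a region larger than the membrane keeps every phosphorus atom
  all_patch <- extract_patch(gm$trajectory, 1, P,
                             fit_region(1e4, 1e4, anchor = "absolute"))
  expect_length(all_patch, length(P))
})

test_that("an off-membrane dimer footprint yields an infeasible patch", {
  b <- make_bundle(n_frames = 2)
  P <- select_atoms(b$traj, name = "P")
  far <- fit_region(anchor = "absolute", absolute_origin = c(500, 0))
  expect_length(extract_patch(b$traj, 1, P, far), 0)
})

test_that("curvature recovery: noiseless window mean is exact", {
  gm <- generate_membrane_trajectory(membrane_spec(
    radius_series = rep(500, 12), noise_sd = 0))
  cs <- curvature_series(gm$trajectory, select_atoms(gm$trajectory, name = "P"),
                         fit_region(anchor = "absolute"))
  expect_equal(attr(cs, "window_mean"), 0.02, tolerance = 1e-9)
  expect_true(all(cs$sign == 1))  # bulge opens toward the protein side
})

test_that("a flat noisy membrane reads as near-zero curvature", {
  gm <- generate_membrane_trajectory(membrane_spec(
    radius_series = rep(Inf, 60), noise_sd = 1, seed = 14))
  cs <- curvature_series(gm$trajectory, select_atoms(gm$trajectory, name = "P"),
                         fit_region(anchor = "absolute"))
  expect_lt(abs(attr(cs, "window_mean")), 0.002)
})

test_that("horizontal displacement ignores z and tracks the bend", {
  # single lipid at (80, 0, z): distance to origin centre is 80 for any z
  atoms <- data.frame(serial = 1:3,
                      name = c("CA", "CA", "P"),
                      element = c("C", "C", "P"),
                      resname = c("GLY", "GLY", "POP"),
                      resno = c(69, 69, 1),
                      chain = c("A", "B", "M"))
  co <- array(0, dim = c(3, 3, 2))
  co[3, , 1] <- c(80, 0, 0)
  co[3, , 2] <- c(80, 0, 37)
  tr <- trajectory(atoms, co)
  ds <- horizontal_displacement_series(tr)
  expect_equal(ds$mean_distance_A, c(80, 80), tolerance = 1e-12)

  # arc-length-preserving bend: distances shrink as R decreases
  gm <- generate_membrane_trajectory(membrane_spec(
    radius_series = seq(4000, 400, length.out = 15), noise_sd = 0))
  dm <- generate_dimer_trajectory(dimer_spec(z_offset = 15),
                                  motion_spec(n_frames = 15,
                                              process = "constant",
                                              core_amplitude = 0))
  bun <- bind_trajectories(dm$trajectory, gm$trajectory)
  ds2 <- horizontal_displacement_series(bun)
  expect_true(all(diff(ds2$mean_distance_A) < 0))

  # static flat run: constant series
  gm3 <- generate_membrane_trajectory(membrane_spec(radius_series = rep(Inf, 5)))
  dm3 <- generate_dimer_trajectory(dimer_spec(z_offset = 15,
                                              arm_angle_series = rep(0, 5)))
  bun3 <- bind_trajectories(dm3$trajectory, gm3$trajectory)
  ds3 <- horizontal_displacement_series(bun3)
  expect_equal(diff(range(ds3$mean_distance_A)), 0, tolerance = 1e-12)
})

test_that("missing centre atoms are a configuration error", {
  gm <- generate_membrane_trajectory(membrane_spec(radius_series = Inf))
  expect_error(horizontal_displacement_series(gm$trajectory),
               "centre atom not found")
})
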