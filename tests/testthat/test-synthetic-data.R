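test_that("flat membranes are exactly planar with zero true curvature", {
  gm <- generate_membrane_trajectory(membrane_spec(radius_series = rep(Inf, 3)))
  expect_true(all(gm$trajectory$coords[, 3, ] == 0))
  expect_true(all(gm$truth$kappa_nm == 0))
})

test_that("bent membrane sagitta matches the closed form", {
  # 21 columns at 8 A spacing span 160 A of arc; R = 500 A
  gm <- generate_membrane_trajectory(membrane_spec(
    nx = 21, ny = 2, radius_series = 500, noise_sd = 0))
  X <- gm$trajectory$coords[, , 1]
  # every bent point satisfies the circle equation z = R - sqrt(R^2 - x^2)
  expect_equal(X[, 3], 500 - sqrt(500^2 - X[, 1]^2), tolerance = 1e-9)
  # edge height: exact arc form R(1 - cos(s/R)), which agrees with the
  # chord form 500 - sqrt(500^2 - 80^2) = 6.44 to within 1% at this radius
  sag_arc <- 500 * (1 - cos(80 / 500))
  expect_equal(max(X[, 3]), sag_arc, tolerance = 1e-9)
  expect_equal(gm$truth$max_sagitta_A[1], sag_arc, tolerance = 1e-9)
  expect_equal(max(X[, 3]), 500 - sqrt(500^2 - 80^2), tolerance = 0.01)
  # arc length is preserved: bent x extent is shorter than flat
  expect_lt(max(X[, 1]), 80)
  expect_equal(max(X[, 1]), 500 * sin(80 / 500), tolerance = 1e-9)
})

test_that("generators are pure functions of spec + seed", {
  s <- membrane_spec(radius_series = rep(700, 4), noise_sd = 0.8, seed = 123)
  expect_identical(generate_membrane_trajectory(s)$trajectory$coords,
                   generate_membrane_trajectory(s)$trajectory$coords)
  d <- dimer_spec(seed = 5)
  m <- motion_spec(n_frames = 20, amplitude = 4, seed = 5)
  expect_identical(generate_dimer_trajectory(d, m)$trajectory$coords,
                   generate_dimer_trajectory(d, m)$trajectory$coords)
  expect_identical(generate_hbond_fixture(2, 2, seed = 3)$coords,
                   generate_hbond_fixture(2, 2, seed = 3)$coords)
})

test_that("a too-small bend radius is rejected (patch cannot wrap)", {
  expect_error(membrane_spec(nx = 43, radius_series = 100),
               "half patch extent")
})

test_that("static arms give constant angles and span", {
  gd <- generate_dimer_trajectory(dimer_spec(arm_angle_series = rep(0, 4)))
  tt <- gd$truth
  expect_equal(diff(range(tt$alpha_true)), 0)
  expect_equal(diff(range(tt$d_true)), 0)
  # base kink 20 deg on both chains: arm axes at 180 - 2*20
  expect_equal(tt$alpha_true[1], 140, tolerance = 1e-9)
  expect_equal(tt$beta_true[1], 180, tolerance = 1e-9)
})

test_that("a symmetric +10 degree swing changes alpha by exactly 20", {
  g0 <- generate_dimer_trajectory(dimer_spec(arm_angle_series = 0))
  g10 <- generate_dimer_trajectory(dimer_spec(arm_angle_series = 10))
  expect_equal(g0$truth$alpha_true[1] - g10$truth$alpha_true[1], 20,
               tolerance = 1e-9)
  # rotation-matrix oracle: angle between the explicitly rotated arm axes
  lift <- function(a) rotation_matrix(c(0, 1, 0), -a)
  c2 <- rotation_matrix(c(0, 0, 1), 180)
  uA <- lift(30) %*% c(1, 0, 0)          # kink 20 + swing 10
  uB <- c2 %*% (lift(30) %*% c(1, 0, 0))
  oracle <- acos(sum(uA * uB)) * 180 / pi
  expect_equal(g10$truth$alpha_true[1], oracle, tolerance = 1e-9)
})

test_that("ground truth is reproduced by independent geometry on the coordinates", {
  gd <- generate_dimer_trajectory(dimer_spec(seed = 8),
                                  motion_spec(n_frames = 6, amplitude = 8,
                                              seed = 8))
  tr <- gd$trajectory
  iA <- select_atoms(tr, chain = "A", resno = 157, name = "CA")
  iB <- select_atoms(tr, chain = "B", resno = 157, name = "CA")
  for (f in seq_len(n_frames(tr))) {
    X <- frame_coords(tr, f)
    expect_equal(sqrt(sum((X[iA, ] - X[iB, ])^2)), gd$truth$d_true[f],
                 tolerance = 1e-9)
  }
})

test_that("an extreme arm rotation that folds the chain is rejected", {
  expect_error(
    generate_dimer_trajectory(dimer_spec(kink_angle = 178,
                                         arm_angle_series = 0)),
    "folds the chain")
})

test_that("hydrogen-bond fixture plants exactly the requested geometry", {
  hb <- generate_hbond_fixture(3, 2, seed = 4)
  don <- select_atoms(hb, name = "NZ")
  acc <- select_atoms(hb, name = "O1")
  expect_length(don, 5)
  expect_length(acc, 5)
  X <- frame_coords(hb)
  da <- sqrt(rowSums((X[don, ] - X[acc, ])^2))
  expect_equal(sort(round(da, 6)), sort(round(c(2.8, 2.8, 2.8, 5, 5), 6)))
})

test_that("sphere fixtures carry their radii and separations", {
  disjoint <- generate_sphere_fixture(2, 2, 100)
  expect_equal(attr(disjoint, "vdw_radius"), c(2, 2))
  coincident <- generate_sphere_fixture(2, 2, 0)
  X <- frame_coords(coincident)
  expect_equal(sqrt(sum((X[1, ] - X[2, ])^2)), 0)
  overlapping <- generate_sphere_fixture(1.9, 1.9, 3.0)
  expect_equal(frame_coords(overlapping)[2, 1], 3)
  expect_error(generate_sphere_fixture(-1, 2, 5), "positive")
})
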