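test_that("isolated and disjoint spheres match the closed forms", {
  sp <- generate_sphere_fixture(1.9, 1.9, 100)
  single <- as.numeric(sasa(sp, 1))
  closed <- 4 * pi * (1.9 + 1.4)^2
  expect_lt(abs(single - closed) / closed, 0.01)
  both <- as.numeric(sasa(sp, 1:2))
  expect_lt(abs(both - 2 * closed) / (2 * closed), 0.01)
})

test_that("overlapping spheres match the spherical-cap closed form", {
  d <- 3.0
  sp <- generate_sphere_fixture(1.9, 1.9, d)
  re <- 1.9 + 1.4
  h <- re - d / 2                       # cap height from the radical plane
  lost_per_sphere <- 2 * pi * re * h
  expected <- 2 * (4 * pi * re^2 - lost_per_sphere)
  got <- as.numeric(sasa(sp, 1:2))
  expect_lt(abs(got - expected) / expected, 0.015)
})

test_that("sasa is invariant under rigid motion", {
  gd <- generate_hbond_fixture(2, 1, seed = 5)
  body <- seq_len(n_atoms(gd))
  s0 <- as.numeric(sasa(gd, body))
  withr::local_seed(55)
  for (i in 1:3) {
    moved <- apply_rigid_traj(gd, random_rigid())
    expect_lt(abs(as.numeric(sasa(moved, body)) - s0) / s0, 0.005)
  }
})

test_that("unknown elements are a named error", {
  atoms <- data.frame(serial = 1, name = "Q1", element = "Qq",
                      resname = "UNK", resno = 1, chain = "A")
  tr <- trajectory(atoms, rbind(c(0, 0, 0)))
  expect_error(sasa(tr, 1), "Qq")
})

test_that("interaction area matches the analytic buried area and is symmetric", {
  sp <- generate_sphere_fixture(1.9, 1.9, 3.0)
  ia <- interaction_area(sp, 1, 2)
  re <- 3.3
  analytic <- 2 * pi * re * (re - 1.5)
  expect_lt(abs(ia$area - analytic) / analytic, 0.02)
  expect_identical(ia$area, interaction_area(sp, 2, 1)$area)
  expect_equal(ia$area, (ia$sasa_A + ia$sasa_B - ia$sasa_AB) / 2,
               tolerance = 1e-12)
})

test_that("far-separated bodies have zero interaction area", {
  sp <- generate_sphere_fixture(2, 2, 100)
  ia <- interaction_area(sp, 1, 2)
  expect_lt(ia$area, 0.5)
})

test_that("overlapping body index sets are rejected", {
  sp <- generate_sphere_fixture(2, 2, 10)
  expect_error(interaction_area(sp, 1:2, 2), "disjoint")
})

test_that("interaction area decays monotonically past contact", {
  seps <- c(3.0, 4.5, 6.0, 6.6, 8, 12)
  areas <- vapply(seps, function(d) {
    interaction_area(generate_sphere_fixture(1.9, 1.9, d), 1, 2)$area
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_lt(areas[length(areas)], 0.5)
})

test_that("planted hydrogen bonds are counted exactly", {
  hb <- generate_hbond_fixture(3, 2, seed = 4)
  don <- select_atoms(hb, name = "NZ")
  acc <- select_atoms(hb, name = "O1")
  bonds <- detect_hbonds(hb, don, acc)
  expect_equal(nrow(bonds), 3)
  expect_identical(attr(bonds, "mode"), "angular")
  none <- generate_hbond_fixture(0, 5, seed = 4)
  expect_equal(nrow(detect_hbonds(none, select_atoms(none, name = "NZ"),
                                  select_atoms(none, name = "O1"))), 0)
  # empty donor/acceptor sets are empty results, not errors
  expect_equal(nrow(detect_hbonds(hb, integer(0), acc)), 0)
})

test_that("the distance cutoff is inclusive at the boundary", {
  hb <- generate_hbond_fixture(1, 0, seed = 2, bonded_da = 3.5)
  bonds <- detect_hbonds(hb, select_atoms(hb, name = "NZ"),
                         select_atoms(hb, name = "O1"))
  expect_equal(nrow(bonds), 1)
  just_out <- generate_hbond_fixture(1, 0, seed = 2, bonded_da = 3.5001)
  expect_equal(nrow(detect_hbonds(just_out,
                                  select_atoms(just_out, name = "NZ"),
                                  select_atoms(just_out, name = "O1"))), 0)
})

test_that("bond counts are monotone in the distance cutoff", {
  hb <- generate_hbond_fixture(3, 3, seed = 8)
  don <- select_atoms(hb, name = "NZ")
  acc <- select_atoms(hb, name = "O1")
  counts <- vapply(c(2, 2.8, 3.5, 5, 6), function(cut) {
    nrow(detect_hbonds(hb, don, acc, hbond_criteria(da_cutoff = cut)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[5], 6)
})

test_that("a topology without hydrogens falls back to distance-only mode", {
  hb <- generate_hbond_fixture(2, 1, seed = 3)
  keep <- which(hb$atoms$element != "H")
  tr <- trajectory(hb$atoms[keep, ], hb$coords[keep, , 1, drop = FALSE])
  bonds <- detect_hbonds(tr, select_atoms(tr, name = "NZ"),
                         select_atoms(tr, name = "O1"))
  expect_identical(attr(bonds, "mode"), "distance_only")
  expect_equal(nrow(bonds), 2)
  expect_true(all(is.na(bonds$angle_deg)))
})

test_that("grouped series attribute bonds to the right clusters", {
  hb <- generate_hbond_fixture(4, 1, seed = 6)
  don <- select_atoms(hb, name = "NZ")
  acc <- select_atoms(hb, name = "O1")
  a <- hb$atoms
  donors_a <- unique(a$resno[a$chain == "A" & a$name == "NZ"])
  donors_b <- unique(a$resno[a$chain == "B" & a$name == "NZ"])
  groups <- list(
    residue_group("g1", data.frame(chain = "A", resno = donors_a)),
    residue_group("g2", data.frame(chain = "B", resno = donors_b)))
  hs <- grouped_hbond_series(hb, groups, don, acc)
  expect_equal(hs$counts$total, 4)
  expect_equal(hs$counts$g1, 2)   # planted bonds alternate A, B, A, B
  expect_equal(hs$counts$g2, 2)
  expect_equal(hs$by_lipid$POP, 4)
  expect_true(hs$counts$g1 + hs$counts$g2 <= hs$counts$total)
})

test_that("all-bonds-in-one-group and absent members behave per contract", {
  hb <- generate_hbond_fixture(3, 2, seed = 9)
  don <- select_atoms(hb, name = "NZ")
  acc <- select_atoms(hb, name = "O1")
  a <- hb$atoms
  nz <- a[a$name == "NZ", ]
  g_all <- residue_group("g1", data.frame(chain = nz$chain, resno = nz$resno))
  hs <- grouped_hbond_series(hb, list(g_all), don, acc)
  expect_equal(hs$counts$g1, 3)
  bad <- residue_group("gx", data.frame(chain = "Z", resno = 999))
  expect_error(grouped_hbond_series(hb, list(bad), don, acc),
               "absent from topology")
})
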