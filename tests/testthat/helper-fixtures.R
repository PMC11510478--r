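# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# hand-rolled PDB text for tiny fixtures (fixed-column ATOM records)
pdb_text <- function(coords, name = "CA", resname = "ALA", chain = "A",
                     element = "C", model = NULL) {
  n <- nrow(coords)
  lines <- sprintf(
    "ATOM  %5d  %-3s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), name, resname, chain, seq_len(n),
    coords[, 1], coords[, 2], coords[, 3], element)
  if (!is.null(model)) {
    lines <- c(sprintf("MODEL     %4d", model), lines, "ENDMDL")
  }
  lines
}

# matching GRO text (nm units, fixed columns)
gro_text <- function(coords_nm, name = "CA", resname = "ALA", time = NULL) {
  n <- nrow(coords_nm)
  title <- if (is.null(time)) "fixture" else sprintf("fixture t= %g", time)
  c(title, sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            seq_len(n), resname, name, seq_len(n),
            coords_nm[, 1], coords_nm[, 2], coords_nm[, 3]),
    "  10.00000  10.00000  10.00000")
}

# independent circle oracle: circumcircle radius of a point triple
circumcircle_radius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  s <- (a + b + cc) / 2
  area <- sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
  if (area == 0) return(Inf)
  a * b * cc / (4 * area)
}

# median circumcircle radius over all point triples
triple_circumcircle_radius <- function(points) {
  n <- nrow(points)
  combos <- utils::combn(n, 3)
  stats::median(apply(combos, 2, function(ix) {
    circumcircle_radius(points[ix[1], ], points[ix[2], ], points[ix[3], ])
  }))
}

# definitional two-pass Pearson formula (independent of stats::cor)
pearson_definitional <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exact points on a circle of radius R centred at `center`
circle_points <- function(R, angles_deg, center = c(0, 0)) {
  th <- angles_deg * pi / 180
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}

# random rigid motion in 3D (rotation + translation), seeded by caller
random_rigid <- function() {
  R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 360))
  t <- stats::rnorm(3, sd = 20)
  list(R = R, t = t)
}

apply_rigid_traj <- function(traj, rigid) {
  for (f in seq_len(n_frames(traj))) {
    traj$coords[, , f] <- sweep(frame_coords(traj, f) %*% t(rigid$R),
                                2, rigid$t, `+`)
  }
  traj
}

# a small membrane+dimer bundle for pipeline tests
make_bundle <- function(n_frames = 30, radius_from = 2000, radius_to = 600,
                        noise_sd = 0, seed = 1) {
  mem <- generate_membrane_trajectory(membrane_spec(
    radius_series = seq(radius_from, radius_to, length.out = n_frames),
    noise_sd = noise_sd, seed = seed))
  dm <- generate_dimer_trajectory(
    dimer_spec(z_offset = 15, seed = seed),
    motion_spec(n_frames = n_frames, amplitude = 3, seed = seed))
  list(traj = bind_trajectories(dm$trajectory, mem$trajectory),
       membrane_truth = mem$truth, dimer_truth = dm$truth)
}
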