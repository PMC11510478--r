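#' Specification for a synthetic bending phosphorus membrane
#'
#' The generator emulates the phosphorus atoms of a lipid patch used as
#' reference points for curvature fitting: a quasi-planar lattice that bends
#' toward a prescribed, possibly time-varying cylindrical radius with
#' additive positional noise.
#'
#' Lattice defaults give a patch of (nx-1) x (ny-1) cells at 8 ångström
#' spacing, about 336 x 88 ångström — the order of the simulated bilayer the
#' analysis is aimed at (~345 x 100 ångström). `nx` is odd so the lattice has
#' columns at x = 0, ±8, …; `ny` is even so rows sit at y = ±4, ±12, …, which
#' puts exactly two rows inside the default 10-ångström-wide fit strip.
#'
#' @param nx,ny Lattice point counts along x and y (`nx * ny >= 12`).
#' @param spacing Lattice spacing in ångström.
#' @param radius_series Per-frame target bend radius R(t) in ångström;
#'   `Inf` means flat. Its length sets the number of frames.
#' @param noise_sd Isotropic Gaussian positional noise sd in ångström.
#' @param dt Frame spacing in ps.
#' @param seed Integer RNG seed; generation is a pure function of spec+seed.
#' @return An object of class `membrane_spec`.
#' @export
membrane_spec <- function(nx = 43, ny = 12, spacing = 8,
                          radius_series = rep(Inf, 10), noise_sd = 0,
                          dt = 100, seed = 1) {
  if (nx * ny < 12) stop("membrane lattice needs nx*ny >= 12 points")
  if (spacing <= 0) stop("spacing must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(radius_series) < 1) stop("radius_series must have >= 1 frame")
  half_extent <- (nx - 1) * spacing / 2
  bad <- which(is.finite(radius_series) & radius_series < half_extent)
  if (length(bad) > 0) {
    stop("radius_series[", bad[1], "] = ", radius_series[bad[1]],
         " angstrom is smaller than the half patch extent (", half_extent,
         " angstrom): the patch would wrap")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
                 radius_series = as.numeric(radius_series),
                 noise_sd = noise_sd, dt = dt, seed = as.integer(seed)),
            class = "membrane_spec")
}

#' Generate a bending-membrane trajectory with ground truth
#'
#' Frame t places pseudo-phosphorus atoms on a cylinder of radius R(t) bent
#' along x. Bending preserves arc length: a lattice point with flat position
#' (x0, y0, 0) maps to `x = R sin(x0/R)`, `z = R (1 - cos(x0/R))`, `y = y0`,
#' i.e. `z = R - sqrt(R^2 - x^2)`, so decreasing R both bulges the patch and
#' contracts it horizontally (centripetal displacement). Isotropic Gaussian
#' noise is added afterwards. Flat frames (R = Inf) have true curvature 0.
#'
#' The membrane bulge opens toward +z, the side on which a bound dimer sits,
#' so the sign convention of [curvature_series()] is +1 on every frame.
#'
#' @param spec A [membrane_spec()].
#' @return List with elements `trajectory` (a [trajectory()]; atoms named
#'   `P`, residue `POP`, chain `M`) and `truth` (data frame with per-frame
#'   `time_ps`, `radius_A`, `kappa_nm` = 10/R, and `max_sagitta_A`).
#' @export
generate_membrane_trajectory <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  set.seed(spec$seed)
  nx <- spec$nx; ny <- spec$ny; s <- spec$spacing
  x0 <- (seq_len(nx) - (nx + 1) / 2) * s
  y0 <- (seq_len(ny) - (ny + 1) / 2) * s
  grid <- expand.grid(x0 = x0, y0 = y0)
  na <- nrow(grid)
  nf <- length(spec$radius_series)
  coords <- array(0, dim = c(na, 3L, nf))
  truth <- data.frame(time_ps = (seq_len(nf) - 1) * spec$dt,
                      radius_A = spec$radius_series,
                      kappa_nm = ifelse(is.finite(spec$radius_series),
                                        10 / spec$radius_series, 0),
                      max_sagitta_A = NA_real_)
  half_extent <- (nx - 1) * s / 2
  for (f in seq_len(nf)) {
    R <- spec$radius_series[f]
    if (is.finite(R)) {
      x <- R * sin(grid$x0 / R)
      z <- R * (1 - cos(grid$x0 / R))
      truth$max_sagitta_A[f] <- R * (1 - cos(half_extent / R))
    } else {
      x <- grid$x0
      z <- rep(0, na)
      truth$max_sagitta_A[f] <- 0
    }
    X <- cbind(x, grid$y0, z)
    if (spec$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(3 * na, sd = spec$noise_sd), na, 3)
    }
    coords[, , f] <- X
  }
  atoms <- data.frame(serial = seq_len(na), name = "P", element = "P",
                      resname = "POP", resno = seq_len(na), chain = "M",
                      stringsAsFactors = FALSE)
  list(trajectory = trajectory(atoms, coords, truth$time_ps), truth = truth)
}
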