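# Small geometric primitives shared by the membrane and dimer modules.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the (not necessarily unit)
#' 3-vector `axis`, right-handed.
#'
#' @param axis Numeric 3-vector.
#' @param angle Rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- unit(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Angle in degrees between two 3-vectors, folded to [0, 180].
angle_between <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# First principal axis of an n x 3 point cloud, unit length.
principal_axis <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 3)
  sv$v[, 1]
}

# Best-fit plane of an n x 3 point cloud: list(centroid, normal).
# Degenerate (collinear or coincident) input raises an error.
fit_plane <- function(X) {
  if (nrow(X) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr), nu = 0, nv = 3)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("membrane points are degenerate (collinear): cannot fit a plane")
  }
  list(centroid = ctr, normal = sv$v[, 3])
}

# Local helix axis of a window of consecutive Calpha positions.
# For residue i in the window interior, p_i = r_{i-1} + r_{i+1} - 2 r_i is
# (for an ideal helix) exactly the inward radial vector, perpendicular to
# the helix axis; the cross product of consecutive p vectors is therefore
# parallel to the axis. Exact on ideal helices of any window length >= 4,
# where PCA of so few atoms is strongly biased by the partial helical turn.
# Returned vector is oriented along increasing residue index (N -> C).
helix_window_axis <- function(X) {
  n <- nrow(X)
  if (n < 4L) stop("helix window axis needs at least 4 residues")
  P <- X[1:(n - 2), , drop = FALSE] + X[3:n, , drop = FALSE] -
    2 * X[2:(n - 1), , drop = FALSE]
  acc <- c(0, 0, 0)
  for (i in seq_len(nrow(P) - 1L)) {
    cr <- cross3(P[i, ], P[i + 1, ])
    nc <- vec_norm(cr)
    if (nc > 1e-12) acc <- acc + cr / nc
  }
  if (vec_norm(acc) < 1e-9) {
    # collinear trace: fall back to the chord
    out <- unit(X[n, ] - X[1, ])
    attr(out, "consistency") <- 1
    return(out)
  }
  ax <- unit(acc)
  if (sum(ax * (X[n, ] - X[1, ])) < 0) ax <- -ax
  # resultant length of the summed unit cross products: 1 when every
  # consecutive pair of normals agrees on the axis (ideal helix window)
  attr(ax, "consistency") <- vec_norm(acc) / (nrow(P) - 1L)
  ax
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(r * cos(phi), r * sin(phi), z)
}
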