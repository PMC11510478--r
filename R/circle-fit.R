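#' Least-squares circle fit in a plane
#'
#' Algebraic (Kåsa) least-squares fit of a circle to 2-D points: solve the
#' linearised circle equation `x^2 + z^2 + D x + E z + F = 0` by ordinary
#' least squares; centre is `(-D/2, -E/2)` and `R = sqrt(D^2/4 + E^2/4 - F)`.
#' Optionally refined by a geometric (orthogonal-residual) Gauss-Newton /
#' Levenberg iteration. Collinear input is mapped to the flat-membrane
#' convention `R = Inf`, curvature 0, rather than an error, so a
#' no-protein control (where frames can be exactly or nearly flat) runs
#' cleanly.
#'
#' Curvature is reported in nm^-1: `kappa = 10 / R` with R in ångström.
#'
#' @param points Numeric `n x 2` matrix (n >= 3) of in-plane coordinates in
#'   ångström.
#' @param refine Logical: run geometric refinement after the algebraic fit
#'   (uses `minpack.lm` if installed, otherwise a plain Gauss-Newton loop).
#' @return An object of class `circle_fit`: list with `center` (2-vector,
#'   ångström; `c(NA, NA)` when flat), `radius` (ångström, may be `Inf`),
#'   `kappa_nm` (nm^-1), `rms_residual` (ångström), `n_points`, and
#'   `method`.
#' @export
fit_circle <- function(points, refine = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an n x 2 matrix")
  if (nrow(points) < 3) stop("circle fit needs at least 3 points")
  x <- points[, 1]; z <- points[, 2]

  # collinearity check on the centred coordinates
  ctr <- c(mean(x), mean(z))
  M <- cbind(x - ctr[1], z - ctr[2])
  sv <- svd(M, nu = 0, nv = 0)$d
  scale <- max(sv[1], 1)
  if (sv[2] < 1e-9 * scale) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          kappa_nm = 0, rms_residual = 0,
                          n_points = nrow(points), method = "collinear"),
                     class = "circle_fit"))
  }

  A <- cbind(x, z, 1)
  b <- -(x^2 + z^2)
  coef <- unname(qr.solve(A, b))
  cx <- -coef[1] / 2
  cz <- -coef[2] / 2
  R2 <- cx^2 + cz^2 - coef[3]
  if (!is.finite(R2) || R2 <= 0) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          kappa_nm = 0, rms_residual = 0,
                          n_points = nrow(points), method = "degenerate"),
                     class = "circle_fit"))
  }
  R <- sqrt(R2)
  method <- "kasa"

  if (refine) {
    par <- c(cx, cz, R)
    resid_fun <- function(p) sqrt((x - p[1])^2 + (z - p[2])^2) - p[3]
    if (requireNamespace("minpack.lm", quietly = TRUE)) {
      fit <- minpack.lm::nls.lm(par, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 100))
      par <- fit$par
    } else {
      for (it in 1:50) {
        r <- resid_fun(par)
        di <- sqrt((x - par[1])^2 + (z - par[2])^2)
        J <- cbind(-(x - par[1]) / di, -(z - par[2]) / di, -1)
        step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 3))
        par <- par + step
        if (max(abs(step)) < 1e-12 * max(abs(par))) break
      }
    }
    cx <- par[1]; cz <- par[2]; R <- abs(par[3])
    method <- "kasa+geometric"
  }

  resid <- sqrt((x - cx)^2 + (z - cz)^2) - R
  structure(list(center = c(cx, cz), radius = R, kappa_nm = 10 / R,
                 rms_residual = sqrt(mean(resid^2)),
                 n_points = nrow(points), method = method),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  if (is.finite(x$radius)) {
    cat(sprintf("circle fit (%s): R = %.3f A, kappa = %.5f /nm, rms = %.4f A, n = %d\n",
                x$method, x$radius, x$kappa_nm, x$rms_residual, x$n_points))
  } else {
    cat(sprintf("circle fit: flat (collinear input), kappa = 0, n = %d\n",
                x$n_points))
  }
  invisible(x)
}

#' Convert between curvature (nm^-1) and fitting-circle radius (nm)
#'
#' The reporting convention defines the radius as the exact reciprocal of
#' the curvature: `R[nm] = 1 / kappa[nm^-1]`.
#'
#' @param kappa_nm Curvature in nm^-1.
#' @param radius_nm Radius in nm.
#' @return The converted value.
#' @export
curvature_to_radius_nm <- function(kappa_nm) 1 / kappa_nm

#' @rdname curvature_to_radius_nm
#' @export
radius_to_curvature_nm <- function(radius_nm) 1 / radius_nm
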