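#' Bondi van der Waals radii (ångström)
#'
#' Default element-to-radius map used by [sasa()].
#'
#' @return Named numeric vector.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Na = 2.27, K = 2.75,
    Mg = 1.73, Ca = 2.31, Zn = 1.39, Fe = 2.00, Se = 1.90)
}

#' SASA parameters
#'
#' @param probe_radius Solvent probe radius in ångström (default 1.4,
#'   a water-sized probe).
#' @param n_sphere_points Number of quasi-uniform test points per atom
#'   (deterministic Fibonacci sphere; >= 100, default 960).
#' @param radii Named element-to-radius map (Bondi defaults).
#' @return An object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii = bondi_radii()) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_sphere_points < 100) stop("n_sphere_points must be >= 100")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii = radii), class = "sasa_params")
}

atom_radii <- function(traj, body, params, radii_override = NULL) {
  if (!is.null(radii_override)) {
    if (length(radii_override) == n_atoms(traj)) {
      return(radii_override[body])
    }
    if (length(radii_override) == length(body)) return(radii_override)
    stop("radii_override length matches neither the body nor the topology")
  }
  elem <- traj$atoms$element[body]
  r <- params$radii[elem]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(elem[is.na(r)]), collapse = ", "))
  }
  as.numeric(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom of the body, `n_sphere_points` quasi-uniform points are
#' placed on its probe-expanded sphere (radius `r_vdw + probe`) and a point
#' counts as accessible if it lies outside every other body atom's expanded
#' sphere. The atom's contribution is the exposed fraction of
#' `4 pi (r + probe)^2`. The point set is deterministic, so results are
#' exactly reproducible.
#'
#' @param traj A [trajectory()].
#' @param body Integer atom indices (non-empty).
#' @param params A [sasa_params()].
#' @param frame Frame index.
#' @param radii_override Optional explicit per-atom radii (used e.g. by the
#'   sphere fixtures, whose pseudo-elements carry their own radii).
#' @return Total SASA in ångström^2, with per-atom values as the
#'   `per_atom` attribute.
#' @export
sasa <- function(traj, body, params = sasa_params(), frame = 1L,
                 radii_override = attr(traj, "vdw_radius")) {
  if (length(body) == 0) stop("body is empty")
  r <- atom_radii(traj, body, params, radii_override)
  re <- r + params$probe_radius
  X <- frame_coords(traj, frame)[body, , drop = FALSE]
  n <- length(body)
  pts <- fibonacci_sphere(params$n_sphere_points)
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(X))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i)
    p <- sweep(pts * re[i], 2, X[i, ], `+`)
    exposed <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (p[, 1] - X[j, 1])^2 + (p[, 2] - X[j, 2])^2 +
        (p[, 3] - X[j, 3])^2
      exposed <- exposed & dj2 > re[j]^2
    }
    per_atom[i] <- 4 * pi * re[i]^2 * mean(exposed)
  }
  structure(sum(per_atom), per_atom = per_atom)
}

#' Pairwise interaction area from SASA
#'
#' The per-partner buried surface on complexation:
#' `area = (SASA_A + SASA_B - SASA_AB) / 2`, symmetric in A and B. Small
#' negative values arising from point-sampling noise are clamped to zero
#' with a warning, never silently.
#'
#' @param traj A [trajectory()].
#' @param body_A,body_B Disjoint integer index sets.
#' @param params A [sasa_params()].
#' @param frame Frame index.
#' @param radii_override Optional explicit per-topology-atom radii.
#' @return An object of class `interaction_area_result`: list with
#'   `sasa_A`, `sasa_B`, `sasa_AB`, `area` (ångström^2) and `clamped`.
#' @export
interaction_area <- function(traj, body_A, body_B, params = sasa_params(),
                             frame = 1L,
                             radii_override = attr(traj, "vdw_radius")) {
  if (length(intersect(body_A, body_B)) > 0) {
    stop("body_A and body_B must be disjoint index sets")
  }
  # per-topology radii so each body resolves its own atoms
  ro <- radii_override
  if (!is.null(ro) && length(ro) != n_atoms(traj)) {
    stop("radii_override must cover the whole topology for interaction_area")
  }
  sA <- as.numeric(sasa(traj, body_A, params, frame, ro))
  sB <- as.numeric(sasa(traj, body_B, params, frame, ro))
  sAB <- as.numeric(sasa(traj, c(body_A, body_B), params, frame, ro))
  area <- (sA + sB - sAB) / 2
  clamped <- FALSE
  if (area < 0) {
    if (area < -1) {
      warning("interaction area is markedly negative (", round(area, 2),
              " A^2); check the body definitions")
    } else {
      warning("small negative interaction area (", signif(area, 3),
              " A^2) from point sampling clamped to 0")
    }
    area <- max(area, 0)
    clamped <- TRUE
  }
  structure(list(sasa_A = sA, sasa_B = sB, sasa_AB = sAB, area = area,
                 clamped = clamped), class = "interaction_area_result")
}

#' @export
print.interaction_area_result <- function(x, ...) {
  cat(sprintf("SASA_A = %.2f, SASA_B = %.2f, SASA_AB = %.2f A^2\n",
              x$sasa_A, x$sasa_B, x$sasa_AB))
  cat(sprintf("interaction area = %.2f A^2%s\n", x$area,
              if (x$clamped) " (clamped)" else ""))
  invisible(x)
}
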