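# Small planted-geometry fixtures used as oracles for the interaction
# module: hydrogen-bond triples with known bonded/non-bonded counts, and
# one- or two-sphere bodies for the SASA / interaction-area closed forms.

#' Generate a hydrogen-bond fixture with known bonded counts
#'
#' Plants `n_bonded` donor-H-acceptor triples in near-linear geometry at a
#' donor-acceptor distance of 2.8 ångström and `n_nonbonded` triples at
#' 5.0 ångström. Donors are lysine side-chain nitrogens (`NZ`, with an
#' attached `HZ1` at 1.0 ångström on the D-A line), acceptors are lipid
#' phosphate oxygens (`O1`, residue `POP`, chain `M`). Triples are spread
#' 20 ångström apart so they cannot cross-talk. The planted donors are
#' split between chains A and B, residues numbered from 19 upward, so the
#' fixture also exercises grouped counting.
#'
#' @param n_bonded,n_nonbonded Numbers of planted triples (>= 0).
#' @param seed Integer RNG seed (randomises triple orientations only).
#' @param bonded_da,nonbonded_da Donor-acceptor distances in ångström.
#' @return A single-frame [trajectory()].
#' @export
generate_hbond_fixture <- function(n_bonded, n_nonbonded, seed = 1,
                                   bonded_da = 2.8, nonbonded_da = 5.0) {
  if (n_bonded < 0 || n_nonbonded < 0) stop("counts must be >= 0")
  set.seed(seed)
  n <- n_bonded + n_nonbonded
  rows <- list()
  coords <- list()
  for (k in seq_len(n)) {
    origin <- c(20 * (k - 1), 0, 0)
    u <- unit(stats::rnorm(3))
    da <- if (k <= n_bonded) bonded_da else nonbonded_da
    chain <- if (k %% 2 == 1) "A" else "B"
    resno <- 19 + (k - 1) %/% 2
    rows[[length(rows) + 1]] <- data.frame(
      name = c("NZ", "HZ1"), element = c("N", "H"),
      resname = "LYS", resno = resno, chain = chain,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <- rbind(origin, origin + 1.0 * u)
    rows[[length(rows) + 1]] <- data.frame(
      name = "O1", element = "O", resname = "POP", resno = 1000 + k,
      chain = "M", stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <- rbind(origin + da * u)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  X <- do.call(rbind, coords)
  trajectory(atoms, X, times = 0)
}

#' Generate a one- or two-sphere body fixture for SASA oracles
#'
#' Two single-atom "bodies" with assigned van der Waals radii, separated by
#' `center_distance` along x. Radii are attached as the `vdw_radius`
#' attribute consumed by [sasa()] / [interaction_area()] via
#' `radii_override`.
#'
#' @param r1,r2 van der Waals radii in ångström (> 0).
#' @param center_distance Separation of the two centres, ångström.
#' @return A single-frame [trajectory()] of two atoms (chains `A` and `B`)
#'   with attribute `vdw_radius` (length-2 numeric).
#' @export
generate_sphere_fixture <- function(r1, r2, center_distance) {
  if (r1 <= 0 || r2 <= 0) stop("radii must be positive")
  atoms <- data.frame(serial = 1:2, name = c("S1", "S2"),
                      element = c("X1", "X2"), resname = "SPH",
                      resno = 1:2, chain = c("A", "B"),
                      stringsAsFactors = FALSE)
  X <- rbind(c(0, 0, 0), c(center_distance, 0, 0))
  traj <- trajectory(atoms, X, times = 0)
  attr(traj, "vdw_radius") <- c(r1, r2)
  traj
}
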