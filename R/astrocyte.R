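#' Count neuroblasts near an astrocytic unit
#'
#' The shrink signal of a unit is driven by the number of distinct
#' neuroblasts whose soma or tip circle surface lies within `d_slit` of the
#' unit surface (surface-to-surface, minimal image). A cell whose soma and
#' tip are both in range still counts once.
#'
#' @param unit_center Unit centre (length-2, um).
#' @param unit_radius Unit radius, um.
#' @param neuroblasts Tibble with columns `soma_x`, `soma_y`, `tip_x`,
#'   `tip_y` (one row per cell).
#' @inheritParams model_params
#' @inheritParams wrap_position
#' @return Integer neighbour count `B`.
#' @export
count_nearby_neuroblasts <- function(unit_center, unit_radius, neuroblasts,
                                     d_slit, field, r_S = 5, r_T = 3) {
  if (nrow(neuroblasts) == 0) return(0L)
  gap <- function(px, py, r) {
    dx <- px - unit_center[1]
    dy <- py - unit_center[2]
    s <- field$side_length
    dx <- dx - s * round(dx / s)
    dy <- dy - s * round(dy / s)
    sqrt(dx^2 + dy^2) - unit_radius - r
  }
  g_soma <- gap(neuroblasts$soma_x, neuroblasts$soma_y, r_S)
  g_tip <- gap(neuroblasts$tip_x, neuroblasts$tip_y, r_T)
  sum(pmin(g_soma, g_tip) <= d_slit)
}

#' Target radius of an astrocytic unit
#'
#' The more neuroblasts signal to a unit, the smaller its target radius:
#' `max(r_max - rho_A * B, r_min)`. With no neighbours the unit re-expands
#' toward `r_max`.
#'
#' @param B Neighbour count(s) (non-negative integers; vectorised).
#' @inheritParams model_params
#' @return Target radius (um).
#' @examples
#' target_radius(5, r_max = 56, rho_A = 5.6, r_min = 28)  # hits the floor
#' @export
target_radius <- function(B, r_max = 28, rho_A = 2.8, r_min = 14) {
  stopifnot(all(B >= 0), r_max > r_min, r_min > 0, rho_A > 0)
  pmax(r_max - rho_A * B, r_min)
}

#' First-order radius relaxation
#'
#' Explicit-Euler step of `tau * dr/dt = r_target - r`, i.e.
#' `r_new = r + (dt / tau) * (r_target - r)`. Requires `dt < tau` for
#' stability.
#'
#' @param r Current radius (um; vectorised).
#' @param r_target Target radius (um).
#' @param tau Time constant, min.
#' @param dt Step, min (must be `< tau`).
#' @return Updated radius (um).
#' @export
relax_radius <- function(r, r_target, tau, dt) {
  if (dt >= tau) stop("relax_radius: dt must be smaller than tau (instability)")
  r + (dt / tau) * (r_target - r)
}

#' Mismatched shrink-signal reassignment
#'
#' In the mismatched-shrinkage control, the per-unit neighbour counts are
#' redistributed over all astrocytic units by a uniformly random
#' permutation, so a unit far from any neuroblast may shrink while a crowded
#' one re-expands. The multiset of counts (hence the total shrink signal and
#' the total astrocyte area, in the long run) is conserved.
#'
#' @param B Integer vector of per-unit neighbour counts (all astrocytes
#'   concatenated).
#' @return Integer vector: the same values under a random permutation.
#' @export
mismatched_reassignment <- function(B) {
  if (length(B) <= 1) return(B)
  B[sample.int(length(B))]
}

#' Velocity of an astrocytic unit under a force
#'
#' Overdamped response: `velocity = force / mu_A`.
#'
#' @param force Length-2 force, nN.
#' @inheritParams model_params
#' @return Length-2 velocity, um/min.
#' @export
astrocyte_unit_velocity <- function(force, mu_A) {
  stopifnot(mu_A > 0)
  force / mu_A
}
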