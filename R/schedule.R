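#' Saltation schedule
#'
#' Describes how the target process length of a neuroblast oscillates: the
#' spring target is `L + A_sal(t) * sin(omega_sal * t + phi_sal)`. The
#' amplitude `A_sal(t)` is constant (`A_mid`), modulated by a slow periodic
#' "activity" wave, or redrawn from a truncated normal every `u` saltation
#' cycles.
#'
#' @inheritParams model_params
#' @param mode `"constant"`, `"periodic"` or `"random"`.
#' @return A list of class `saltation_schedule`.
#' @examples
#' sched <- saltation_schedule("periodic")
#' target_length(0, sched)
#' @export
saltation_schedule <- function(mode = c("constant", "periodic", "random"),
                               L = 40, A_mid = 10, omega_sal = 2 * pi / 20,
                               A_act = 5, omega_act = omega_sal / 36,
                               phi_act = 3 * pi / 2,
                               sigma_A = 5, u = 3,
                               amplitude_bounds = c(0, 20)) {
  mode <- match.arg(mode)
  stopifnot(A_mid >= 0, sigma_A >= 0, u >= 1,
            amplitude_bounds[1] <= A_mid, A_mid <= amplitude_bounds[2])
  structure(list(mode = mode, L = L, A_mid = A_mid, omega_sal = omega_sal,
                 A_act = A_act, omega_act = omega_act, phi_act = phi_act,
                 sigma_A = sigma_A, u = as.integer(u),
                 amplitude_bounds = amplitude_bounds),
            class = "saltation_schedule")
}

#' @rdname saltation_schedule
#' @param schedule A [saltation_schedule()].
#' @param t Time(s), min.
#' @param current_amplitude Amplitude currently in force (random mode only).
#' @return `saltation_amplitude()`: the amplitude `A_sal(t)` in um,
#'   vectorised over `t`.
#' @export
saltation_amplitude <- function(t, schedule, current_amplitude = NULL) {
  switch(schedule$mode,
    constant = rep_len(schedule$A_mid, length(t)),
    periodic = schedule$A_mid +
      schedule$A_act * sin(schedule$omega_act * t + schedule$phi_act),
    random = {
      stopifnot(!is.null(current_amplitude))
      rep_len(current_amplitude, length(t))
    })
}

#' Target process length
#'
#' The spring target `L + A_sal(t) * sin(omega_sal * t + phi_sal)`.
#' Vectorised over `t`.
#'
#' @inheritParams saltation_amplitude
#' @param phi_sal Initial saltation phase of the cell, rad.
#' @return Target length(s), um.
#' @examples
#' sched <- saltation_schedule("constant")
#' range(target_length(seq(0, 20, by = 0.01), sched))  # 30 .. 50
#' @export
target_length <- function(t, schedule, phi_sal = 0, current_amplitude = NULL) {
  A <- saltation_amplitude(t, schedule, current_amplitude)
  schedule$L + A * sin(schedule$omega_sal * t + phi_sal)
}

#' Redraw a random-mode saltation amplitude
#'
#' Draws from Normal(`A_mid`, `sigma_A`) and clamps into
#' `amplitude_bounds`. Clamping a distribution symmetric about the interval
#' midpoint preserves the mean, so the long-run average target length still
#' equals `L`.
#'
#' @inheritParams saltation_amplitude
#' @param n Number of draws.
#' @return Amplitude draw(s), um, inside `amplitude_bounds`.
#' @export
redraw_random_amplitude <- function(schedule, n = 1) {
  stopifnot(schedule$mode == "random")
  b <- schedule$amplitude_bounds
  pmin(pmax(stats::rnorm(n, schedule$A_mid, schedule$sigma_A), b[1]), b[2])
}

#' Saltation phase: resting or moving
#'
#' A cell is resting while its target length is non-decreasing (the process
#' extends and the soma is anchored) and moving while it decreases (the tip
#' is anchored and the soma translocates). The derivative is taken at fixed
#' amplitude; a derivative of exactly zero (including the amplitude-free
#' case) counts as resting.
#'
#' @inheritParams target_length
#' @return Character vector `"resting"`/`"moving"`, vectorised over `t`.
#' @export
saltation_phase <- function(t, schedule, phi_sal = 0,
                            current_amplitude = NULL) {
  A <- saltation_amplitude(t, schedule, current_amplitude)
  deriv <- A * schedule$omega_sal * cos(schedule$omega_sal * t + phi_sal)
  ifelse(deriv >= 0, "resting", "moving")
}

#' Friction pair for a saltation phase
#'
#' The anchoring switch: in the moving phase the soma slides
#' (`mu_low`) while the tip grips (`mu_high`); in the resting phase the
#' roles swap. Requires `mu_high > mu_low > 0`.
#'
#' @param phase `"resting"` or `"moving"` (scalar or vector).
#' @inheritParams model_params
#' @return A tibble with columns `phase`, `mu_soma`, `mu_tip`.
#' @export
friction_pair <- function(phase, mu_low = 1, mu_high = 100) {
  stopifnot(mu_high > mu_low, mu_low > 0, all(phase %in% c("resting", "moving")))
  tibble::tibble(phase = phase,
                 mu_soma = ifelse(phase == "moving", mu_low, mu_high),
                 mu_tip = ifelse(phase == "moving", mu_high, mu_low))
}

#' Spring force pair on soma and tip
#'
#' The process spring pulls the soma-tip separation `l` toward the target
#' length: the soma feels `k_P * (l - l_target)` along the unit vector soma
#' to tip, the tip feels the opposite. Forces always sum to zero.
#'
#' @param soma,tip Wrapped positions (length-2, um).
#' @param l_target Target length, um.
#' @inheritParams model_params
#' @inheritParams wrap_position
#' @return List with `on_soma` and `on_tip` (length-2 forces, nN).
#' @export
spring_forces <- function(soma, tip, l_target, k_P, field) {
  d <- minimal_image(tip, soma, field)
  l <- sqrt(sum(d^2))
  if (l == 0) stop("degenerate neuroblast axis: soma and tip coincide")
  e <- d / l
  f <- k_P * (l - l_target) * e
  list(on_soma = f, on_tip = -f)
}

#' Adhesion-strength schedule between neuroblasts
#'
#' Temporal modulation of the neuroblast-neuroblast adhesion `H_N` around a
#' fixed mean, mirroring the amplitude schedules: periodic adds a slow sine
#' (clamped at zero), random redraws from Normal(`H_mid`, `sigma_H`) clamped
#' into `[0, 2 H_mid]` every `u` saltation cycles.
#'
#' @param mode `"constant"`, `"periodic"` or `"random"`.
#' @param H_mid Mean adhesion strength, nN.
#' @inheritParams model_params
#' @return A list of class `adhesion_schedule`.
#' @export
adhesion_schedule <- function(mode = c("constant", "periodic", "random"),
                              H_mid = 2.22, A_H = 8,
                              omega_act = (2 * pi / 20) / 36,
                              phi_act = 3 * pi / 2, sigma_H = 4, u_H = 3) {
  mode <- match.arg(mode)
  stopifnot(H_mid >= 0, sigma_H >= 0, u_H >= 1)
  structure(list(mode = mode, H_mid = H_mid, A_H = A_H,
                 omega_act = omega_act, phi_act = phi_act,
                 sigma_H = sigma_H, u_H = as.integer(u_H)),
            class = "adhesion_schedule")
}

#' @rdname adhesion_schedule
#' @param t Time(s), min.
#' @param schedule An [adhesion_schedule()].
#' @param current_value Adhesion value currently in force (random mode).
#' @return `adhesion_strength()`: `H_N(t)` in nN (never negative),
#'   vectorised over `t`.
#' @export
adhesion_strength <- function(t, schedule, current_value = NULL) {
  switch(schedule$mode,
    constant = rep_len(schedule$H_mid, length(t)),
    periodic = pmax(0, schedule$H_mid +
                      schedule$A_H * sin(schedule$omega_act * t +
                                           schedule$phi_act)),
    random = {
      stopifnot(!is.null(current_value))
      rep_len(current_value, length(t))
    })
}

#' @rdname adhesion_schedule
#' @param n Number of draws.
#' @return `redraw_random_adhesion()`: draw(s) clamped into `[0, 2 H_mid]`.
#' @export
redraw_random_adhesion <- function(schedule, n = 1) {
  stopifnot(schedule$mode == "random")
  pmin(pmax(stats::rnorm(n, schedule$H_mid, schedule$sigma_H), 0),
       2 * schedule$H_mid)
}
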