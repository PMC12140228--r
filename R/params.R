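#' Model parameters
#'
#' Bundles every numeric constant of the neuroblast-astrocyte model. Defaults
#' reproduce the baseline parameterisation: neuroblast geometry and saltation
#' timing from in vitro morphology (process length `L = 40` um, soma and tip
#' radii 5 and 3 um, process half-width 2 um, a 20-min saltation cycle),
#' signalling range `d_slit = 15` um, and neuroblast-neuroblast adhesion
#' `H_N = 2.22` nN. Constants that are only constrained qualitatively
#' (frictions, spring and repulsion stiffness, astrocyte shrinkage rates,
#' astrocyte adhesions) default to values chosen once to satisfy those
#' constraints; see the methods vignette for the rationale of each.
#'
#' @param L Middle (average) process length, um.
#' @param r_S,r_T Soma and tip radii, um.
#' @param w Half-width of the process rectangle, um.
#' @param A_mid Middle saltation amplitude, um.
#' @param omega_sal Saltation angular velocity, rad/min (20-min cycle).
#' @param A_act Activity amplitude for the periodic amplitude schedule, um.
#' @param omega_act Activity angular velocity, rad/min. The default
#'   `omega_sal / 36` gives a 12-h activity cycle.
#' @param phi_act Activity initial phase, rad.
#' @param sigma_A Standard deviation of the random amplitude schedule, um.
#' @param u Number of saltation cycles between random redraws.
#' @param amplitude_bounds Truncation interval for random amplitudes, um.
#' @param mu_low,mu_high Low/high friction coefficients of the anchoring
#'   switch, nN min/um. Must satisfy `mu_high > mu_low > 0`.
#' @param k_P Process spring constant, nN/um.
#' @param k_R Repulsion coefficient, nN/um of overlap.
#' @param H_N Neuroblast-neuroblast adhesion strength, nN.
#' @param H_A Adhesion between units of different astrocytes, nN.
#' @param H_a Adhesion between units of one astrocyte, nN; must exceed `H_A`
#'   substantially so an astrocyte never splits.
#' @param A_H,sigma_H,u_H Periodic amplitude, random standard deviation and
#'   redraw interval (saltation cycles) for the inconstant-adhesion
#'   schedules.
#' @param n_units Astrocytic units per astrocyte (3, or 1 for the
#'   single-unit morphology variant).
#' @param r_max,r_min Maximum and minimum unit radius, um.
#' @param rho_A Radius decrement per nearby neuroblast, um.
#' @param tau Time constant of radius relaxation, min.
#' @param mu_A Friction coefficient of an astrocytic unit, nN min/um.
#' @param d_slit Signalling range: a neuroblast within this
#'   surface-to-surface distance of a unit counts toward its shrinkage, um.
#' @param count_process If `TRUE`, the process rectangle also counts toward
#'   `d_slit` proximity (off by default: only soma and tip circles count).
#' @param mismatch_interval Minutes between permutation refreshes in the
#'   mismatched-shrinkage mode (one saltation period by default).
#' @param adhesion_law `"constant"` (adhesion is a constant-magnitude pull
#'   while circles overlap) or `"proportional"` (adhesion scales with the
#'   overlap, for sensitivity checks).
#' @param side_length Field side, um.
#' @param d_near Collectivity radius: another neuroblast within this
#'   surface-to-surface distance counts as a neighbour, um.
#' @param t_eval Forward-speed evaluation interval, min.
#' @return A list of class `model_params`.
#' @examples
#' p <- model_params()
#' p$H_N
#' @export
model_params <- function(L = 40, r_S = 5, r_T = 3, w = 2,
                         A_mid = 10, omega_sal = 2 * pi / 20,
                         A_act = 5, omega_act = omega_sal / 36,
                         phi_act = 3 * pi / 2,
                         sigma_A = 5, u = 3, amplitude_bounds = c(0, 20),
                         mu_low = 1, mu_high = 100, k_P = 0.5, k_R = 10,
                         H_N = 2.22, H_A = 0.56, H_a = 22.2,
                         A_H = 8, sigma_H = 4, u_H = 3,
                         n_units = 3, r_max = 28, r_min = 14, rho_A = 2.8,
                         tau = 30, mu_A = 1000, d_slit = 15,
                         count_process = FALSE, mismatch_interval = 20,
                         adhesion_law = c("constant", "proportional"),
                         side_length = 600, d_near = 20, t_eval = 60) {
  adhesion_law <- match.arg(adhesion_law)
  p <- as.list(environment())
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(p$mu_high > p$mu_low && p$mu_low > 0,
      "friction coefficients must satisfy mu_high > mu_low > 0")
  chk(p$k_P > 0, "spring constant k_P must be positive")
  chk(p$k_R > 0, "repulsion coefficient k_R must be positive")
  chk(p$L > p$r_S + p$r_T,
      "process length L must exceed r_S + r_T (non-degenerate dumbbell)")
  chk(p$r_max > p$r_min && p$r_min > 0,
      "astrocyte radii must satisfy r_max > r_min > 0")
  chk(p$rho_A > 0, "shrinkage increment rho_A must be positive")
  chk(p$tau > 0, "relaxation time constant tau must be positive")
  chk(p$d_slit >= 0, "signalling range d_slit must be non-negative")
  chk(p$H_N >= 0 && p$H_A >= 0 && p$H_a >= 0,
      "adhesion strengths must be non-negative")
  chk(p$H_a > p$H_A,
      "intra-astrocyte adhesion H_a must exceed inter-astrocyte H_A")
  chk(p$A_mid >= 0 && p$sigma_A >= 0, "amplitudes must be non-negative")
  chk(p$u >= 1 && p$u == round(p$u), "redraw interval u must be an integer >= 1")
  chk(length(p$amplitude_bounds) == 2 &&
        p$amplitude_bounds[1] <= p$A_mid &&
        p$A_mid <= p$amplitude_bounds[2],
      "amplitude_bounds must contain A_mid")
  chk(p$n_units %in% c(1L, 3L), "n_units must be 1 or 3")
  chk(p$mu_A > 0, "astrocyte friction mu_A must be positive")
  chk(p$side_length > 2 * (p$L + p$amplitude_bounds[2] + p$r_S + p$r_T),
      "field side must exceed twice the largest agent extent")
  invisible(p)
}

#' Simulation run configuration
#'
#' Combines [model_params()] with the condition flags of a simulation run:
#' agent counts, duration, integration step, schedule modes and
#' initialization. The returned object fully determines a run given a seed.
#'
#' Morphology variants adjust the parameters: `"smooth_neuroblast"` sets
#' `r_S = r_T = w = 5` um (a rounded rectangle), `"single_unit_astrocyte"`
#' sets `n_units = 1` with `r_max = 56`, `r_min = 28`, `rho_A = 5.6` um (an
#' exact circle whose area matches the three-unit territory).
#'
#' @param params A [model_params()] object.
#' @param n_neuroblasts Number of neuroblasts (24 in the baseline).
#' @param n_astrocytes Number of astrocytes (0, 10, 20, 30 or 40 in the
#'   baseline sweep; any non-negative integer accepted).
#' @param duration Trial duration, min (9000 = 150 h in the baseline).
#' @param dt Integration step, min. Validated against the stability bound
#'   `min(mu_low / k_P, tau) / 10`.
#' @param output_interval Minutes between trajectory frames.
#' @param n_trials Number of trials per condition.
#' @param base_seed Integer; trial `k` uses seed `base_seed + k`.
#' @param shrink_mode `"reactive"` (units shrink with their own neighbour
#'   count) or `"mismatched"` (neighbour counts are randomly permuted across
#'   units, conserving total shrinkage).
#' @param amplitude_schedule `"constant"`, `"periodic"` or `"random"`
#'   saltation amplitude.
#' @param adhesion_schedule `"constant"`, `"periodic"` or `"random"`
#'   neuroblast-neuroblast adhesion strength.
#' @param morphology `"default"`, `"smooth_neuroblast"` or
#'   `"single_unit_astrocyte"`.
#' @param init_mode `"scattered"` (uniform random, non-overlapping
#'   neuroblasts) or `"clustered"` (all neuroblasts packed in a central
#'   disc).
#' @param cluster_radius Radius of the central disc for clustered
#'   initialization, um.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(n_astrocytes = 0, duration = 100, n_trials = 1)
#' @export
run_config <- function(params = model_params(),
                       n_neuroblasts = 24, n_astrocytes = 40,
                       duration = 9000, dt = 0.02, output_interval = 60,
                       n_trials = 10, base_seed = 1,
                       shrink_mode = c("reactive", "mismatched"),
                       amplitude_schedule = c("constant", "periodic", "random"),
                       adhesion_schedule = c("constant", "periodic", "random"),
                       morphology = c("default", "smooth_neuroblast",
                                      "single_unit_astrocyte"),
                       init_mode = c("scattered", "clustered"),
                       cluster_radius = 60) {
  shrink_mode <- match.arg(shrink_mode)
  amplitude_schedule <- match.arg(amplitude_schedule)
  adhesion_schedule <- match.arg(adhesion_schedule)
  morphology <- match.arg(morphology)
  init_mode <- match.arg(init_mode)
  stopifnot(inherits(params, "model_params"))
  if (morphology == "smooth_neuroblast") {
    params$r_S <- params$r_T <- params$w <- 5
  } else if (morphology == "single_unit_astrocyte") {
    params$n_units <- 1L
    params$r_max <- 56
    params$r_min <- 28
    params$rho_A <- 5.6
  }
  cfg <- list(params = params, n_neuroblasts = as.integer(n_neuroblasts),
              n_astrocytes = as.integer(n_astrocytes),
              duration = duration, dt = dt,
              output_interval = output_interval,
              n_trials = as.integer(n_trials),
              base_seed = as.integer(base_seed),
              shrink_mode = shrink_mode,
              amplitude_schedule = amplitude_schedule,
              adhesion_schedule = adhesion_schedule,
              morphology = morphology, init_mode = init_mode,
              cluster_radius = cluster_radius)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  p <- cfg$params
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  validate_model_params(p)
  chk(cfg$n_neuroblasts >= 1, "need at least one neuroblast")
  chk(cfg$n_astrocytes >= 0, "n_astrocytes must be non-negative")
  chk(cfg$duration > 0, "duration must be positive")
  bound <- min(p$mu_low / p$k_P, p$tau) / 10
  chk(cfg$dt > 0 && cfg$dt <= bound,
      sprintf("dt must satisfy 0 < dt <= %.4g (stability bound min(mu_low/k_P, tau)/10)",
              bound))
  steps <- cfg$duration / cfg$dt
  chk(abs(steps - round(steps)) < 1e-8, "duration must be a multiple of dt")
  spo <- cfg$output_interval / cfg$dt
  chk(abs(spo - round(spo)) < 1e-8,
      "output_interval must be a multiple of dt")
  chk(cfg$n_trials >= 1, "n_trials must be at least 1")
  invisible(cfg)
}

#' Expand a condition grid into run configurations
#'
#' Takes one value vector per swept flag and returns a tibble with one row
#' per combination plus a list-column `config` of complete [run_config()]
#' objects, ready for [run_sweep()].
#'
#' @param n_astrocytes,shrink_mode,amplitude_schedule,adhesion_schedule,H_N,morphology,init_mode
#'   Vectors of values to sweep (defaults: single baseline value each).
#' @param params Base [model_params()]; `H_N` values override its adhesion.
#' @param ... Further arguments passed to [run_config()] (e.g. `duration`,
#'   `n_trials`, `base_seed`, `dt`).
#' @return A tibble with the flag columns and a `config` list-column.
#' @examples
#' g <- condition_grid(n_astrocytes = c(0, 40), duration = 100, n_trials = 1)
#' nrow(g)
#' @export
condition_grid <- function(n_astrocytes = 40,
                           shrink_mode = "reactive",
                           amplitude_schedule = "constant",
                           adhesion_schedule = "constant",
                           H_N = 2.22,
                           morphology = "default",
                           init_mode = "scattered",
                           params = model_params(), ...) {
  grid <- tidyr::expand_grid(n_astrocytes = n_astrocytes,
                             shrink_mode = shrink_mode,
                             amplitude_schedule = amplitude_schedule,
                             adhesion_schedule = adhesion_schedule,
                             H_N = H_N,
                             morphology = morphology,
                             init_mode = init_mode)
  grid$config <- purrr::pmap(grid, function(n_astrocytes, shrink_mode,
                                            amplitude_schedule,
                                            adhesion_schedule, H_N,
                                            morphology, init_mode) {
    p <- params
    p$H_N <- H_N
    run_config(params = p, n_astrocytes = n_astrocytes,
               shrink_mode = shrink_mode,
               amplitude_schedule = amplitude_schedule,
               adhesion_schedule = adhesion_schedule,
               morphology = morphology, init_mode = init_mode, ...)
  })
  grid
}
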