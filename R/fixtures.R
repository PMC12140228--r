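#' Deterministic test scenarios
#'
#' Hand-built small initial states for fast, reproducible checks of the
#' contact mechanics:
#'
#' * `"solitary_free"`: one neuroblast, no astrocytes - free saltatory
#'   locomotion.
#' * `"dimer_collision"`: two neuroblasts on slightly offset colliding
#'   courses - with no adhesion they pass and separate, with moderate
#'   adhesion they stay neighbours.
#' * `"corridor"`: three neuroblasts in single file aimed at the gap
#'   between two flanking astrocytes.
#' * `"antialigned_pair"`: two neuroblasts exactly head-on.
#'
#' @param name Fixture name.
#' @param params A [model_params()] (fixtures scale with `L` and `r_max`).
#' @return A list of class `sim_fixture` with `name`, `state` (as from
#'   [initialize_state()]) and `config_args` (suggested [run_config()]
#'   overrides: agent counts and init-free flag).
#' @examples
#' fx <- make_fixture("corridor")
#' nrow(fx$state$neuroblasts)
#' @export
make_fixture <- function(name = c("solitary_free", "dimer_collision",
                                  "corridor", "antialigned_pair"),
                         params = model_params()) {
  name <- match.arg(name)
  p <- params
  c0 <- p$side_length / 2
  nb_row <- function(id, soma, angle) {
    tip <- soma + p$L * c(cos(angle), sin(angle))
    tibble::tibble(cell_id = id, soma_x = soma[1], soma_y = soma[2],
                   tip_x = tip[1], tip_y = tip[2], phi_sal = 0)
  }
  astro_at <- function(id, centre, angle0 = pi / 2) {
    if (p$n_units == 3) {
      angs <- angle0 + c(0, 2, 4) * pi / 3
      ux <- centre[1] + 0.8 * p$r_max * cos(angs)
      uy <- centre[2] + 0.8 * p$r_max * sin(angs)
    } else {
      ux <- centre[1]; uy <- centre[2]
    }
    tibble::tibble(astro_id = id, unit = seq_along(ux), x = ux, y = uy,
                   radius = p$r_max)
  }
  empty_astro <- tibble::tibble(astro_id = integer(), unit = integer(),
                                x = numeric(), y = numeric(),
                                radius = numeric())
  state <- switch(name,
    solitary_free = list(
      neuroblasts = nb_row(1L, c(c0 - p$L / 2, c0), 0),
      astrocytes = empty_astro),
    dimer_collision = list(
      neuroblasts = dplyr::bind_rows(
        nb_row(1L, c(c0 - 60, c0), 0),
        nb_row(2L, c(c0 + 60, c0 + 6), pi)),
      astrocytes = empty_astro),
    corridor = list(
      neuroblasts = dplyr::bind_rows(
        nb_row(1L, c(c0 - 30, c0), 0),
        nb_row(2L, c(c0 - 80, c0), 0),
        nb_row(3L, c(c0 - 130, c0), 0)),
      astrocytes = dplyr::bind_rows(
        astro_at(1L, c(c0 + 40, c0 - (1.8 * p$r_max + 12))),
        astro_at(2L, c(c0 + 40, c0 + 1.8 * p$r_max + 12), -pi / 2))),
    antialigned_pair = list(
      neuroblasts = dplyr::bind_rows(
        nb_row(1L, c(c0 - 70, c0), 0),
        nb_row(2L, c(c0 + 70, c0), pi)),
      astrocytes = empty_astro))
  n_astro <- if (nrow(state$astrocytes)) max(state$astrocytes$astro_id) else 0L
  structure(list(name = name, state = state,
                 config_args = list(
                   n_neuroblasts = nrow(state$neuroblasts),
                   n_astrocytes = n_astro)),
            class = "sim_fixture")
}

#' Run a fixture scenario
#'
#' Convenience wrapper: builds a [run_config()] matching the fixture's
#' agent counts and integrates it from the hand-built state.
#'
#' @param fixture A [make_fixture()] object (or fixture name).
#' @param duration,output_interval Minutes.
#' @param params A [model_params()].
#' @param ... Passed to [run_config()] (e.g. `amplitude_schedule`).
#' @return A trajectory tibble.
#' @export
run_fixture <- function(fixture, duration = 200, output_interval = 20,
                        params = model_params(), ...) {
  if (is.character(fixture)) fixture <- make_fixture(fixture, params)
  cfg <- run_config(params = params,
                    n_neuroblasts = fixture$config_args$n_neuroblasts,
                    n_astrocytes = fixture$config_args$n_astrocytes,
                    duration = duration, output_interval = output_interval,
                    n_trials = 1, ...)
  simulate_trial(cfg, trial = 1, init_state = fixture$state)
}
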