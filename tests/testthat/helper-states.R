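# Shared test scaffolding: small hand-built states, a synthetic trajectory
# generator for the evaluation layer, and a cache for the scaled-down
# condition runs shared by the acceptance blocks.

f600 <- field_spec(600)

# a neuroblast row in the state format used by assemble_forces()
nb_state <- function(cell_id, soma, tip, l_target = 40, phi_sal = 0) {
  tibble::tibble(cell_id = cell_id, soma_x = soma[1], soma_y = soma[2],
                 tip_x = tip[1], tip_y = tip[2], phi_sal = phi_sal,
                 l_target = l_target)
}

astro_state <- function(astro_id, unit, x, y, radius) {
  tibble::tibble(astro_id = astro_id, unit = unit, x = x, y = y,
                 radius = radius)
}

no_astro <- astro_state(integer(), integer(), numeric(), numeric(), numeric())

# a crowded random state for oracle-equivalence checks: somas/tips and
# astrocyte units compressed into a patch so that many contacts occur
random_crowded_state <- function(n_nb = 8, n_astro = 4, seed = 1,
                                 params = model_params()) {
  set.seed(seed)
  centre <- 300
  spread <- 55
  soma <- matrix(centre + runif(2 * n_nb, -spread, spread), ncol = 2)
  ang <- runif(n_nb, 0, 2 * pi)
  nb <- tibble::tibble(
    cell_id = seq_len(n_nb),
    soma_x = soma[, 1], soma_y = soma[, 2],
    tip_x = soma[, 1] + params$L * cos(ang),
    tip_y = soma[, 2] + params$L * sin(ang),
    phi_sal = runif(n_nb, 0, 2 * pi),
    l_target = 40 + 10 * sin(runif(n_nb, 0, 2 * pi)))
  astro <- NULL
  if (n_astro > 0) {
    cen <- matrix(centre + runif(2 * n_astro, -2 * spread, 2 * spread),
                  ncol = 2)
    rows <- lapply(seq_len(n_astro), function(a) {
      a0 <- runif(1, 0, 2 * pi)
      angs <- a0 + c(0, 2, 4) * pi / 3
      tibble::tibble(astro_id = a, unit = 1:3,
                     x = cen[a, 1] + 0.8 * params$r_max * cos(angs),
                     y = cen[a, 2] + 0.8 * params$r_max * sin(angs),
                     radius = runif(3, params$r_min, params$r_max))
    })
    astro <- dplyr::bind_rows(rows)
  } else {
    astro <- no_astro
  }
  list(neuroblasts = nb, astrocytes = astro)
}

# synthetic trajectory: cells gliding at constant speed along their own
# axis, spaced far apart (collectivity 0), in the exact trajectory-table
# format produced by simulate_trial()
gliding_trajectory <- function(n_cells = 24, times = seq(0, 9000, by = 60),
                               speed = 1, trial = 1, side = 600) {
  gx <- ((seq_len(n_cells) - 1) %% 6) * 100 + 30
  gy <- ((seq_len(n_cells) - 1) %/% 6) * 140 + 30
  rows <- lapply(seq_along(times), function(k) {
    t <- times[k]
    ux <- speed * t
    sx <- (gx + ux) %% side
    tibble::tibble(
      trial = trial, t_min = t, agent_kind = "neuroblast",
      agent_id = rep(seq_len(n_cells), 2),
      circle_role = rep(c("soma", "tip"), each = n_cells),
      x_um = c(sx, (sx + 40) %% side), y_um = rep(gy, 2),
      radius_um = rep(c(5, 3), each = n_cells),
      unwrapped_dx = c(rep(ux, n_cells), rep(NA_real_, n_cells)),
      unwrapped_dy = c(rep(0, n_cells), rep(NA_real_, n_cells)),
      B = NA_integer_, A_sal = 10, H_N_t = 2.22)
  })
  dplyr::bind_rows(rows)
}

# Scaled-down condition runs shared by the end-to-end checks of the
# collectivity-slope contrast. Cached so several test blocks reuse one
# set of simulations.
.cond_cache <- new.env(parent = emptyenv())

condition_fit <- function(n_astrocytes, amplitude_schedule,
                          n_trials = 3, duration = 3000, base_seed = 100) {
  key <- paste(n_astrocytes, amplitude_schedule, n_trials, duration,
               base_seed, sep = "_")
  if (!is.null(.cond_cache[[key]])) return(.cond_cache[[key]])
  cfg <- run_config(n_astrocytes = n_astrocytes,
                    amplitude_schedule = amplitude_schedule,
                    duration = duration, n_trials = n_trials,
                    base_seed = base_seed)
  traj <- run_condition(cfg)
  samples <- collect_samples(traj, window = c(900, duration))
  fit <- fit_speed_collectivity(samples)
  .cond_cache[[key]] <- fit
  fit
}
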