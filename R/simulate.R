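#' Build an initial simulation state
#'
#' Scattered mode draws uniform positions and orientations for the
#' neuroblasts, rejection-sampling until no neuroblast circle overlaps any
#' previously placed circle; astrocytes are then placed with their units at
#' the vertices of an equilateral triangle (circumradius `0.8 * r_max`)
#' around a uniform centre, radii at `r_max`, rejection-sampled so that no
#' unit overlaps a neuroblast soma or tip. Astrocyte-astrocyte overlap is
#' permitted at t = 0 (at high densities full mutual exclusion is
#' geometrically infeasible; their own repulsion relaxes residual overlap).
#' Clustered mode packs all neuroblast somas inside a central disc and
#' keeps astrocyte units outside it. Saltation phases are i.i.d. uniform on
#' `[0, 2 pi)`.
#'
#' @param config A [run_config()].
#' @param seed Integer seed (determines the state completely).
#' @return A list with tibbles `neuroblasts` (`cell_id`, `soma_x`,
#'   `soma_y`, `tip_x`, `tip_y`, `phi_sal`) and `astrocytes` (`astro_id`,
#'   `unit`, `x`, `y`, `radius`).
#' @export
initialize_state <- function(config, seed = config$base_seed) {
  p <- config$params
  field <- field_spec(p$side_length)
  set.seed(seed)
  s <- p$side_length
  clustered <- config$init_mode == "clustered"
  centre <- c(s / 2, s / 2)
  max_try <- 1e5

  placed_x <- numeric(0)
  placed_y <- numeric(0)
  placed_r <- numeric(0)
  clear_of_placed <- function(x, y, r) {
    if (length(placed_x) == 0) return(TRUE)
    dx <- placed_x - x
    dy <- placed_y - y
    dx <- dx - s * round(dx / s)
    dy <- dy - s * round(dy / s)
    all(dx^2 + dy^2 > (placed_r + r)^2)
  }

  nb <- matrix(NA_real_, config$n_neuroblasts, 5)
  for (i in seq_len(config$n_neuroblasts)) {
    ok <- FALSE
    for (try in seq_len(max_try)) {
      if (clustered) {
        rad <- config$cluster_radius * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        soma <- wrap_position(centre + rad * c(cos(ang), sin(ang)), field)
      } else {
        soma <- stats::runif(2, 0, s)
      }
      theta <- stats::runif(1, 0, 2 * pi)
      tip <- wrap_position(soma + p$L * c(cos(theta), sin(theta)), field)
      if (clear_of_placed(soma[1], soma[2], p$r_S) &&
          clear_of_placed(tip[1], tip[2], p$r_T)) {
        nb[i, ] <- c(soma, tip, stats::runif(1, 0, 2 * pi))
        placed_x <- c(placed_x, soma[1], tip[1])
        placed_y <- c(placed_y, soma[2], tip[2])
        placed_r <- c(placed_r, p$r_S, p$r_T)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("initialization failed: field too crowded for neuroblasts")
  }

  n_units <- p$n_units
  astro <- NULL
  if (config$n_astrocytes > 0) {
    astro <- matrix(NA_real_, config$n_astrocytes * n_units, 4)
    row <- 1
    for (a in seq_len(config$n_astrocytes)) {
      ok <- FALSE
      for (try in seq_len(max_try)) {
        cen <- stats::runif(2, 0, s)
        if (n_units == 3) {
          ang0 <- stats::runif(1, 0, 2 * pi)
          angs <- ang0 + c(0, 2, 4) * pi / 3
          ux <- cen[1] + 0.8 * p$r_max * cos(angs)
          uy <- cen[2] + 0.8 * p$r_max * sin(angs)
        } else {
          ux <- cen[1]
          uy <- cen[2]
        }
        good <- TRUE
        for (k in seq_len(n_units)) {
          if (!clear_of_placed(ux[k], uy[k], p$r_max)) { good <- FALSE; break }
          if (clustered) {
            d <- sqrt(sum((minimal_image(c(ux[k], uy[k]), centre, field))^2))
            if (d < config$cluster_radius + p$r_max) { good <- FALSE; break }
          }
        }
        if (good) {
          wpos <- wrap_position(cbind(ux, uy), field)
          astro[row:(row + n_units - 1), ] <-
            cbind(a, seq_len(n_units), wpos)
          row <- row + n_units
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("initialization failed: field too crowded for astrocytes")
    }
  }

  list(
    neuroblasts = tibble::tibble(
      cell_id = seq_len(config$n_neuroblasts),
      soma_x = nb[, 1], soma_y = nb[, 2],
      tip_x = nb[, 3], tip_y = nb[, 4], phi_sal = nb[, 5]),
    astrocytes = if (is.null(astro)) {
      tibble::tibble(astro_id = integer(), unit = integer(),
                     x = numeric(), y = numeric(), radius = numeric())
    } else {
      tibble::tibble(astro_id = as.integer(astro[, 1]),
                     unit = as.integer(astro[, 2]),
                     x = astro[, 3], y = astro[, 4],
                     radius = p$r_max)
    })
}

mode_code <- function(x) {
  match(x, c("constant", "periodic", "random")) - 1L
}

engine_pars <- function(config) {
  p <- config$params
  list(side = p$side_length, r_S = p$r_S, r_T = p$r_T, w = p$w, L = p$L,
       A_mid = p$A_mid, omega_sal = p$omega_sal, A_act = p$A_act,
       omega_act = p$omega_act, phi_act = p$phi_act, sigma_A = p$sigma_A,
       u = as.integer(p$u), amp_lo = p$amplitude_bounds[1],
       amp_hi = p$amplitude_bounds[2], mu_low = p$mu_low,
       mu_high = p$mu_high, k_P = p$k_P, k_R = p$k_R, H_N = p$H_N,
       A_H = p$A_H, sigma_H = p$sigma_H, u_H = as.integer(p$u_H),
       H_A = p$H_A, H_a = p$H_a, r_max = p$r_max, r_min = p$r_min,
       rho_A = p$rho_A, tau = p$tau, mu_A = p$mu_A, d_slit = p$d_slit,
       mismatch_interval = p$mismatch_interval,
       amp_mode = mode_code(config$amplitude_schedule),
       adh_mode = mode_code(config$adhesion_schedule),
       shrink_mode = if (config$shrink_mode == "mismatched") 1L else 0L,
       law = if (p$adhesion_law == "proportional") 1L else 0L)
}

#' Run one seeded simulation trial
#'
#' Integrates the coupled overdamped system from 0 to `duration` with
#' explicit Euler at step `dt`, writing a trajectory frame every
#' `output_interval` minutes. The trial seed is `base_seed + trial`, used
#' for initialization and for every in-run random draw (amplitude and
#' adhesion redraws, mismatched permutations, degenerate-contact
#' directions), so reruns are bit-identical.
#'
#' @param config A [run_config()].
#' @param trial Trial index (1-based).
#' @param init_state Optional pre-built state (as from
#'   [initialize_state()] or [make_fixture()]); defaults to a fresh seeded
#'   initialization.
#' @return A tibble with one row per circle per output frame: `trial`,
#'   `t_min`, `agent_kind`, `agent_id`, `circle_role`, `x_um`, `y_um`,
#'   `radius_um`, `unwrapped_dx`, `unwrapped_dy`, `B`, `A_sal`, `H_N_t`.
#'   Attributes `config`, `seed` and `max_step_disp` (largest single-step
#'   circle displacement, um) are attached.
#' @examples
#' cfg <- run_config(n_astrocytes = 0, n_neuroblasts = 2, duration = 40,
#'                   output_interval = 20, n_trials = 1)
#' traj <- simulate_trial(cfg, trial = 1)
#' @export
simulate_trial <- function(config, trial = 1, init_state = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$base_seed + as.integer(trial)
  state <- if (is.null(init_state)) initialize_state(config, seed) else init_state
  nb <- state$neuroblasts
  as_tab <- state$astrocytes
  nb_mat <- cbind(nb$soma_x, nb$soma_y, nb$tip_x, nb$tip_y, nb$phi_sal, 0)
  res <- engine_run(nb_mat, as_tab$x, as_tab$y, as_tab$radius,
                    as.integer(as_tab$astro_id), engine_pars(config),
                    config$duration, config$dt, config$output_interval,
                    seed)
  p <- config$params
  n_frames <- length(res$times)
  nbm <- res$nb
  hn <- rep(res$h_n, each = nrow(nb))
  soma_rows <- tibble::tibble(
    trial = trial, t_min = nbm[, 1], agent_kind = "neuroblast",
    agent_id = as.integer(nbm[, 2]), circle_role = "soma",
    x_um = nbm[, 3], y_um = nbm[, 4], radius_um = p$r_S,
    unwrapped_dx = nbm[, 7], unwrapped_dy = nbm[, 8],
    B = NA_integer_, A_sal = nbm[, 9], H_N_t = hn)
  tip_rows <- tibble::tibble(
    trial = trial, t_min = nbm[, 1], agent_kind = "neuroblast",
    agent_id = as.integer(nbm[, 2]), circle_role = "tip",
    x_um = nbm[, 5], y_um = nbm[, 6], radius_um = p$r_T,
    unwrapped_dx = NA_real_, unwrapped_dy = NA_real_,
    B = NA_integer_, A_sal = nbm[, 9], H_N_t = hn)
  out <- dplyr::bind_rows(soma_rows, tip_rows)
  if (nrow(as_tab) > 0) {
    am <- res$astro
    unit_within <- rep(as_tab$unit, times = n_frames)
    astro_rows <- tibble::tibble(
      trial = trial, t_min = am[, 1], agent_kind = "astrocyte",
      agent_id = as.integer(am[, 2]),
      circle_role = paste0("unit_", unit_within),
      x_um = am[, 4], y_um = am[, 5], radius_um = am[, 6],
      unwrapped_dx = NA_real_, unwrapped_dy = NA_real_,
      B = as.integer(am[, 7]), A_sal = NA_real_,
      H_N_t = rep(res$h_n, each = nrow(as_tab)))
    out <- dplyr::bind_rows(out, astro_rows)
  }
  out <- dplyr::arrange(out, .data$t_min, .data$agent_kind, .data$agent_id,
                        .data$circle_role)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "max_step_disp") <- res$max_step_disp
  out
}

#' Run all trials of one condition
#'
#' @inheritParams simulate_trial
#' @param trials Trial indices (defaults to `1:n_trials` from the config).
#' @return A trajectory tibble (all trials row-bound), with the `config`
#'   attribute attached.
#' @export
run_condition <- function(config, trials = seq_len(config$n_trials)) {
  out <- dplyr::bind_rows(lapply(trials, function(k) simulate_trial(config, k)))
  attr(out, "config") <- config
  out
}

#' Run a condition grid and regress each condition
#'
#' For every row of a [condition_grid()] this runs all trials, collects
#' evaluation samples and fits the forward-speed-on-collectivity
#' regression, returning the slope table that underlies the condition heat
#' maps.
#'
#' @param grid A tibble from [condition_grid()] (needs a `config`
#'   list-column).
#' @param window,interval Evaluation window and spacing passed to
#'   [collect_samples()]; the window defaults to
#'   `c(900, duration)` of each config.
#' @param verbose Print one line per finished condition.
#' @return The grid with list-column `fit` plus numeric columns `alpha`,
#'   `alpha_se`, `beta`, `beta_se`, `n_samples`.
#' @export
run_sweep <- function(grid, window = NULL, interval = 60, verbose = FALSE) {
  stopifnot("config" %in% names(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- grid$config[[i]]
    traj <- run_condition(cfg)
    win <- if (is.null(window)) c(900, cfg$duration) else window
    samples <- collect_samples(traj, window = win, interval = interval)
    fits[[i]] <- fit_speed_collectivity(samples)
    if (verbose) {
      message(sprintf("condition %d/%d: alpha = %.3f", i, nrow(grid),
                      fits[[i]]$slope))
    }
  }
  grid$fit <- fits
  grid$alpha <- vapply(fits, function(f) f$slope, numeric(1))
  grid$alpha_se <- vapply(fits, function(f) f$slope_se, numeric(1))
  grid$beta <- vapply(fits, function(f) f$intercept, numeric(1))
  grid$beta_se <- vapply(fits, function(f) f$intercept_se, numeric(1))
  grid$n_samples <- vapply(fits, function(f) f$n_samples, numeric(1))
  grid
}

#' Flatten a sweep result to a plain slope table
#'
#' Drops the list-columns so the result round-trips through CSV losslessly;
#' one row per condition with the regression slope, intercept, standard
#' errors and sample size (the tabular form of the condition heat maps).
#'
#' @param sweep Result of [run_sweep()].
#' @return A plain tibble without list-columns.
#' @export
sweep_table <- function(sweep) {
  keep <- !vapply(sweep, is.list, logical(1))
  tibble::as_tibble(sweep[, keep, drop = FALSE])
}
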