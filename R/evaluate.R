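#' Forward speed of every neuroblast at every frame
#'
#' The migration-efficiency measure: the soma displacement over the last
#' `t_eval` minutes (taken from the unwrapped accumulator, so it is
#' boundary-safe) projected onto the soma-to-tip unit axis evaluated at the
#' window end, divided by `t_eval`. Straight forward gliding along the axis
#' gives the soma speed; diagonal motion is down-weighted by the projection
#' and backward motion is negative.
#'
#' @param trajectory A trajectory tibble from [simulate_trial()] or
#'   [run_condition()].
#' @param t_eval Evaluation interval, min; must be a multiple of the
#'   trajectory's frame spacing.
#' @return A tibble `trial`, `cell_id`, `t`, `forward_speed` (um/min) for
#'   every frame with a frame `t_eval` earlier available.
#' @export
forward_speeds <- function(trajectory, t_eval = 60) {
  cfg <- attr(trajectory, "config")
  side <- if (!is.null(cfg)) cfg$params$side_length else 600
  somas <- dplyr::filter(trajectory, .data$agent_kind == "neuroblast",
                         .data$circle_role == "soma")
  tips <- dplyr::filter(trajectory, .data$agent_kind == "neuroblast",
                        .data$circle_role == "tip")
  df <- dplyr::inner_join(
    dplyr::select(somas, "trial", "t_min", "agent_id",
                  sx = "x_um", sy = "y_um",
                  udx = "unwrapped_dx", udy = "unwrapped_dy"),
    dplyr::select(tips, "trial", "t_min", "agent_id",
                  tx = "x_um", ty = "y_um"),
    by = c("trial", "t_min", "agent_id"))
  frame_dt <- unique(round(diff(sort(unique(df$t_min))), 9))
  stopifnot(length(frame_dt) >= 1)
  lag_k <- t_eval / frame_dt[1]
  if (abs(lag_k - round(lag_k)) > 1e-8) {
    stop("t_eval must be a multiple of the trajectory frame spacing")
  }
  lag_k <- as.integer(round(lag_k))
  df <- dplyr::arrange(df, .data$trial, .data$agent_id, .data$t_min)
  df <- dplyr::group_by(df, .data$trial, .data$agent_id)
  df <- dplyr::mutate(df,
    ex = {
      d <- .data$tx - .data$sx
      d - side * round(d / side)
    },
    ey = {
      d <- .data$ty - .data$sy
      d - side * round(d / side)
    },
    el = sqrt(.data$ex^2 + .data$ey^2),
    forward_speed = (.data$ex / .data$el *
                       (.data$udx - dplyr::lag(.data$udx, lag_k)) +
                     .data$ey / .data$el *
                       (.data$udy - dplyr::lag(.data$udy, lag_k))) / t_eval)
  df <- dplyr::ungroup(df)
  out <- dplyr::filter(df, !is.na(.data$forward_speed))
  dplyr::select(out, "trial", cell_id = "agent_id", t = "t_min",
                "forward_speed")
}

#' Collectivity of every neuroblast at selected frames
#'
#' Counts, for each neuroblast, the other neuroblasts whose closest
#' surface-to-surface distance (minimum over the four soma/tip circle
#' pairs, minimal image) is at most `d_near`. The boundary is inclusive
#' and the relation symmetric.
#'
#' @inheritParams forward_speeds
#' @param d_near Neighbour radius, um.
#' @param at Frame times to evaluate (default: all frames).
#' @return A tibble `trial`, `cell_id`, `t`, `collectivity`.
#' @export
collectivity <- function(trajectory, d_near = 20, at = NULL) {
  cfg <- attr(trajectory, "config")
  side <- if (!is.null(cfg)) cfg$params$side_length else 600
  nb <- dplyr::filter(trajectory, .data$agent_kind == "neuroblast")
  if (!is.null(at)) nb <- dplyr::filter(nb, .data$t_min %in% at)
  frames <- dplyr::group_split(dplyr::group_by(nb, .data$trial, .data$t_min))
  res <- lapply(frames, function(fr) {
    somas <- fr[fr$circle_role == "soma", ]
    tips <- fr[fr$circle_role == "tip", ]
    tips <- tips[match(somas$agent_id, tips$agent_id), ]
    n <- nrow(somas)
    counts <- integer(n)
    if (n > 1) {
      px <- cbind(somas$x_um, tips$x_um)
      py <- cbind(somas$y_um, tips$y_um)
      pr <- cbind(somas$radius_um, tips$radius_um)
      mind <- matrix(Inf, n, n)
      for (a in 1:2) {
        for (b in 1:2) {
          dx <- outer(px[, a], px[, b], "-")
          dy <- outer(py[, a], py[, b], "-")
          dx <- dx - side * round(dx / side)
          dy <- dy - side * round(dy / side)
          gap <- sqrt(dx^2 + dy^2) - outer(pr[, a], pr[, b], "+")
          mind <- pmin(mind, gap)
        }
      }
      diag(mind) <- Inf
      counts <- as.integer(rowSums(mind <= d_near))
    }
    tibble::tibble(trial = somas$trial, cell_id = somas$agent_id,
                   t = somas$t_min, collectivity = counts)
  })
  dplyr::bind_rows(res)
}

#' Collect evaluation samples from trajectories
#'
#' Builds the (forward speed, collectivity) sample table over the
#' evaluation window: one sample per trial, cell and evaluation time. The
#' default window of 900 to 9000 min at 60-min spacing yields 136 time
#' points per trial; trials whose frames do not span the window are
#' excluded with a warning.
#'
#' @inheritParams forward_speeds
#' @inheritParams collectivity
#' @param window Length-2 numeric: first and last evaluation time, min.
#' @param interval Spacing of evaluation times, min.
#' @return A tibble `trial`, `cell_id`, `t`, `forward_speed`,
#'   `collectivity`.
#' @export
collect_samples <- function(trajectory, window = c(900, 9000), interval = 60,
                            t_eval = 60, d_near = 20) {
  eval_times <- seq(window[1], window[2], by = interval)
  have <- dplyr::distinct(
    dplyr::filter(trajectory, .data$agent_kind == "neuroblast",
                  .data$circle_role == "soma"),
    .data$trial, .data$t_min)
  need <- unique(c(eval_times, eval_times - t_eval))
  ok_trials <- vapply(split(have$t_min, have$trial),
                      function(ts) all(need %in% ts), logical(1))
  bad <- names(ok_trials)[!ok_trials]
  if (length(bad) > 0) {
    warning("excluding incomplete trial(s): ", paste(bad, collapse = ", "))
    trajectory <- dplyr::filter(trajectory,
                                !.data$trial %in% as.integer(bad))
  }
  vs <- forward_speeds(trajectory, t_eval = t_eval)
  vs <- dplyr::filter(vs, .data$t %in% eval_times)
  ns <- collectivity(trajectory, d_near = d_near, at = eval_times)
  dplyr::inner_join(vs, ns, by = c("trial", "cell_id", "t"))
}

#' Regress forward speed on collectivity
#'
#' Pooled ordinary least squares of forward speed on collectivity across
#' all trials of one condition (no per-trial weighting): a positive slope
#' means neuroblasts in collectives outpace solitary ones. Also computes
#' per-collectivity mean speeds with normal-approximation 95% confidence
#' intervals for the binned-means plot.
#'
#' @param samples Sample tibble from [collect_samples()].
#' @return An object of class `collectivity_fit`: list with `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `n_samples`, the binned-means
#'   tibble `binned`, and the underlying `lm` fit. With fewer than two
#'   distinct collectivity values the slope is `NA` (degenerate design).
#' @export
fit_speed_collectivity <- function(samples) {
  stopifnot(all(c("forward_speed", "collectivity") %in% names(samples)))
  binned <- dplyr::summarise(
    dplyr::group_by(samples, .data$collectivity),
    mean_speed = mean(.data$forward_speed),
    se = stats::sd(.data$forward_speed) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  binned$ci_lo <- binned$mean_speed - 1.96 * binned$se
  binned$ci_hi <- binned$mean_speed + 1.96 * binned$se
  if (length(unique(samples$collectivity)) < 2) {
    out <- list(fit = NULL, slope = NA_real_, slope_se = NA_real_,
                intercept = mean(samples$forward_speed),
                intercept_se = NA_real_, n_samples = nrow(samples),
                binned = binned)
    class(out) <- "collectivity_fit"
    return(out)
  }
  fit <- stats::lm(forward_speed ~ collectivity, data = samples)
  co <- summary(fit)$coefficients
  out <- list(fit = fit,
              slope = co["collectivity", "Estimate"],
              slope_se = co["collectivity", "Std. Error"],
              intercept = co["(Intercept)", "Estimate"],
              intercept_se = co["(Intercept)", "Std. Error"],
              n_samples = nrow(samples), binned = binned)
  class(out) <- "collectivity_fit"
  out
}

#' @export
print.collectivity_fit <- function(x, ...) {
  cat("Forward speed ~ collectivity (pooled OLS)\n")
  cat(sprintf("  slope alpha:     %8.4f um/min per neighbour (SE %.4f)\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept beta:  %8.4f um/min (SE %.4f)\n",
              x$intercept, x$intercept_se))
  cat(sprintf("  n samples:       %d\n", x$n_samples))
  invisible(x)
}
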