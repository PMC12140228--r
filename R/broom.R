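#' Tidy a collectivity regression
#'
#' @param x A `collectivity_fit` from [fit_speed_collectivity()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.collectivity_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("(Intercept)", "collectivity"),
                          estimate = c(x$intercept, NA_real_),
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, "Estimate"]),
                 std.error = unname(co[, "Std. Error"]),
                 statistic = unname(co[, "t value"]),
                 p.value = unname(co[, "Pr(>|t|)"]))
}

#' Glance at a collectivity regression
#'
#' @inheritParams tidy.collectivity_fit
#' @return A one-row tibble: `alpha` (slope), `alpha_se`, `beta`
#'   (intercept), `beta_se`, `r.squared`, `n_samples`.
#' @export
glance.collectivity_fit <- function(x, ...) {
  tibble::tibble(alpha = x$slope, alpha_se = x$slope_se,
                 beta = x$intercept, beta_se = x$intercept_se,
                 r.squared = if (is.null(x$fit)) NA_real_
                             else summary(x$fit)$r.squared,
                 n_samples = x$n_samples)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Binned-means plot of a collectivity regression
#'
#' Mean forward speed per collectivity value with 95% confidence
#' intervals, overlaid with the pooled regression line.
#'
#' @param object A `collectivity_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.collectivity_fit <- function(object, ...) {
  b <- object$binned
  gg <- ggplot2::ggplot(b, ggplot2::aes(x = .data$collectivity,
                                        y = .data$mean_speed)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "collectivity n (neighbours within 20 µm)",
                  y = "forward speed v (µm/min)") +
    ggplot2::theme_minimal()
  if (!is.na(object$slope)) {
    gg <- gg + ggplot2::geom_abline(intercept = object$intercept,
                                    slope = object$slope,
                                    linetype = "dashed")
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map of regression slopes over a condition grid
#'
#' @param sweep A [run_sweep()] result (or [sweep_table()] output).
#' @param x,y Names of the condition columns to place on the axes.
#' @return A ggplot tile plot of the slope `alpha` (blue positive, red
#'   negative), the graphical form of the condition slope tables.
#' @export
plot_slope_grid <- function(sweep, x = "amplitude_schedule",
                            y = "n_astrocytes") {
  stopifnot(all(c(x, y, "alpha") %in% names(sweep)))
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = factor(.data[[x]]),
                               y = factor(.data[[y]]),
                               fill = .data$alpha)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$alpha))) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = x, y = y, fill = "slope α") +
    ggplot2::theme_minimal()
}

#' Snapshot of the simulation field
#'
#' Draws every circle (somas, tips, astrocytic units) of one trajectory
#' frame as true-scale circles, with the process segments.
#'
#' @param trajectory A trajectory tibble.
#' @param t Frame time to draw (defaults to the last frame).
#' @param trial Trial to draw.
#' @return A ggplot object with fixed aspect ratio.
#' @export
plot_field <- function(trajectory, t = max(trajectory$t_min), trial = 1) {
  fr <- trajectory[trajectory$t_min == t & trajectory$trial == trial, ]
  if (nrow(fr) == 0) stop("no frame at t = ", t, " for trial ", trial)
  circle_poly <- function(x, y, r, id, kind) {
    th <- seq(0, 2 * pi, length.out = 48)
    tibble::tibble(px = rep(x, each = 48) + rep(r, each = 48) * cos(th),
                   py = rep(y, each = 48) + rep(r, each = 48) * sin(th),
                   grp = rep(id, each = 48), kind = rep(kind, each = 48))
  }
  polys <- circle_poly(fr$x_um, fr$y_um, fr$radius_um,
                       paste(fr$agent_kind, fr$agent_id, fr$circle_role),
                       fr$agent_kind)
  somas <- fr[fr$circle_role == "soma", ]
  tips <- fr[fr$circle_role == "tip", ]
  tips <- tips[match(somas$agent_id, tips$agent_id), ]
  # draw the process to the soma's nearest periodic image of the tip so
  # segments never streak across the whole field
  cfg <- attr(trajectory, "config")
  side <- if (!is.null(cfg)) cfg$params$side_length else 600
  dx <- tips$x_um - somas$x_um
  dy <- tips$y_um - somas$y_um
  segs <- tibble::tibble(x = somas$x_um, y = somas$y_um,
                         xend = somas$x_um + dx - side * round(dx / side),
                         yend = somas$y_um + dy - side * round(dy / side))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(.data$px, .data$py, group = .data$grp,
                                       fill = .data$kind),
                          colour = "grey30", alpha = 0.6) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                       yend = .data$yend),
                          linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(neuroblast = "palegreen3",
                                          astrocyte = "lightsalmon")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("t = %g min", t)) +
    ggplot2::theme_minimal()
}
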