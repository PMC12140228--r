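test_that("forward speed projects the 60-min soma displacement on the axis", {
  # gliding cells: displacement exactly along the axis at 1 um/min
  tr <- gliding_trajectory(n_cells = 4, times = seq(0, 300, by = 60),
                           speed = 1)
  vs <- forward_speeds(tr)
  expect_equal(unique(round(vs$forward_speed, 12)), 1)
  expect_equal(nrow(vs), 4 * 5)  # all frames except t = 0
  # stationary cells score zero
  tr0 <- gliding_trajectory(n_cells = 3, times = seq(0, 120, by = 60),
                            speed = 0)
  expect_equal(max(abs(forward_speeds(tr0)$forward_speed)), 0)
  # perpendicular displacement projects to zero: move the unwrapped path
  # sideways while the axis stays along x
  trp <- gliding_trajectory(n_cells = 2, times = seq(0, 120, by = 60),
                            speed = 0)
  trp$unwrapped_dy[trp$circle_role == "soma"] <-
    trp$t_min[trp$circle_role == "soma"]  # 60 um north per hour
  expect_equal(max(abs(forward_speeds(trp)$forward_speed)), 0)
})

test_that("collectivity counts symmetric inclusive surface neighbours", {
  mk <- function(soma_xs, y = 300) {
    n <- length(soma_xs)
    tibble::tibble(
      trial = 1L, t_min = 0, agent_kind = "neuroblast",
      agent_id = rep(seq_len(n), 2),
      circle_role = rep(c("soma", "tip"), each = n),
      x_um = c(soma_xs, soma_xs + 40), y_um = y,
      radius_um = rep(c(5, 3), each = n),
      unwrapped_dx = 0, unwrapped_dy = 0, B = NA_integer_,
      A_sal = 10, H_N_t = 2.22)
  }
  # solitary cell
  expect_equal(collectivity(mk(300))$collectivity, 0L)
  # soma surfaces 10 um apart (centres 150 apart: tip1 at 190+3, soma2 at 200-5... )
  # use two parallel cells with soma centres 20 um apart: surface gap 10
  tr <- mk(c(300, 320))
  # soma1-soma2 centres 20 apart, radii 5+5 -> gap 10 <= 20: neighbours
  cc <- collectivity(tr)
  expect_equal(cc$collectivity, c(1L, 1L))
  # exact boundary: soma surfaces exactly 20 um apart (inclusive tie-break)
  tr2 <- tibble::tibble(
    trial = 1L, t_min = 0, agent_kind = "neuroblast",
    agent_id = rep(1:2, 2), circle_role = rep(c("soma", "tip"), each = 2),
    x_um = c(300, 300, 340, 340), y_um = c(300, 330, 300, 330),
    radius_um = rep(c(5, 3), each = 2),
    unwrapped_dx = 0, unwrapped_dy = 0, B = NA_integer_,
    A_sal = 10, H_N_t = 2.22)
  expect_equal(collectivity(tr2)$collectivity, c(1L, 1L))
  expect_equal(collectivity(tr2, d_near = 19.999)$collectivity, c(0L, 0L))
  # far-apart cells are not neighbours
  tr3 <- mk(c(100, 400))
  expect_equal(collectivity(tr3)$collectivity, c(0L, 0L))
})

test_that("sample collection yields 136 evaluation points per trial", {
  tr <- gliding_trajectory(n_cells = 24, times = seq(0, 9000, by = 60))
  s <- collect_samples(tr)
  expect_equal(nrow(s), 24 * 136)
  expect_equal(length(unique(s$t)), 136)
  expect_equal(range(s$t), c(900, 9000))
  # a single-time window keeps one time point per cell
  s1 <- collect_samples(tr, window = c(900, 900))
  expect_equal(nrow(s1), 24)
  # pooling trials concatenates samples
  tr2 <- gliding_trajectory(n_cells = 24, times = seq(0, 9000, by = 60),
                            trial = 2)
  s1e <- collect_samples(dplyr::bind_rows(tr, tr2))
  expect_equal(nrow(s1e), 2 * 24 * 136)
  # incomplete trials are dropped with a warning
  short <- gliding_trajectory(n_cells = 24, times = seq(0, 3000, by = 60),
                              trial = 3)
  expect_warning(s2 <- collect_samples(dplyr::bind_rows(tr, short)),
                 "incomplete")
  expect_equal(nrow(s2), 24 * 136)
})

test_that("the pooled regression matches the normal-equation oracle", {
  # exact linear relationship recovers the coefficients
  s <- tibble::tibble(trial = 1L, cell_id = 1L, t = 1,
                      collectivity = rep(0:5, each = 10))
  s$forward_speed <- 2 * s$collectivity + 1
  f <- suppressWarnings(fit_speed_collectivity(s))  # lm warns on exact fits
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  # constant speed gives zero slope
  s$forward_speed <- 0.7
  expect_equal(suppressWarnings(fit_speed_collectivity(s))$slope, 0,
               tolerance = 1e-12)
  # random samples against the closed-form normal equations
  set.seed(13)
  s <- tibble::tibble(trial = 1L, cell_id = 1L, t = 1,
                      collectivity = rpois(200, 2),
                      forward_speed = rnorm(200, 0.5, 0.3))
  f <- fit_speed_collectivity(s)
  X <- cbind(1, s$collectivity)
  beta <- solve(t(X) %*% X, t(X) %*% s$forward_speed)
  expect_equal(f$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f$slope, beta[2], tolerance = 1e-10)
  # degenerate design: all collectivity equal -> slope undefined
  sdeg <- tibble::tibble(trial = 1, cell_id = 1, t = 1,
                         collectivity = 1L, forward_speed = rnorm(10))
  fdeg <- fit_speed_collectivity(sdeg)
  expect_true(is.na(fdeg$slope))
})

test_that("binned means carry normal-approximation confidence intervals", {
  set.seed(14)
  s <- tibble::tibble(trial = 1L, cell_id = 1L, t = 1,
                      collectivity = rep(c(0L, 1L), each = 50),
                      forward_speed = rnorm(100))
  f <- fit_speed_collectivity(s)
  b0 <- f$binned[f$binned$collectivity == 0, ]
  grp <- s$forward_speed[s$collectivity == 0]
  expect_equal(b0$mean_speed, mean(grp))
  expect_equal(b0$ci_hi - b0$mean_speed, 1.96 * sd(grp) / sqrt(50))
  expect_equal(b0$n, 50)
})

test_that("tidy, glance and autoplot summarise the fit", {
  s <- tibble::tibble(trial = 1L, cell_id = 1L, t = 1,
                      collectivity = rep(0:3, each = 5),
                      forward_speed = rnorm(20, 0.5))
  f <- fit_speed_collectivity(s)
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "collectivity"))
  expect_equal(td$estimate[2], f$slope)
  gl <- glance(f)
  expect_equal(gl$alpha, f$slope)
  expect_equal(gl$n_samples, 20)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("sweep tables flatten and round-trip through CSV", {
  g <- condition_grid(n_astrocytes = c(0, 10), amplitude_schedule =
                        c("constant", "periodic"), duration = 100,
                      n_trials = 1)
  expect_equal(nrow(g), 4)
  g$fit <- replicate(4, list(slope = 0.1), simplify = FALSE)
  g$alpha <- c(0.1, -0.2, 0.3, 0)
  tab <- sweep_table(g)
  expect_false(any(vapply(tab, is.list, logical(1))))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tab, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
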