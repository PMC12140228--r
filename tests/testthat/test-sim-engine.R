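test_that("initialization is seeded, non-overlapping and mode-aware", {
  cfg <- run_config(n_neuroblasts = 12, n_astrocytes = 4, duration = 20,
                    n_trials = 1)
  s1 <- initialize_state(cfg, seed = 3)
  s2 <- initialize_state(cfg, seed = 3)
  expect_identical(s1, s2)
  s3 <- initialize_state(cfg, seed = 4)
  expect_false(identical(s1, s3))
  # neuroblast circles overlap nothing at t = 0
  nb <- s1$neuroblasts
  circ <- rbind(cbind(nb$soma_x, nb$soma_y, 5), cbind(nb$tip_x, nb$tip_y, 3),
                cbind(s1$astrocytes$x, s1$astrocytes$y, 28))
  n_nbc <- 2 * nrow(nb)
  for (i in seq_len(n_nbc)) {
    for (j in seq_len(nrow(circ))[-i]) {
      if (i > n_nbc && j > n_nbc) next
      d <- sqrt(sum(minimal_image(circ[i, 1:2], circ[j, 1:2], f600)^2))
      if (j <= n_nbc || i <= n_nbc) {
        expect_gte(d, circ[i, 3] + circ[j, 3] - 1e-9)
      }
    }
  }
  # clustered mode packs all somas in the central disc, astrocytes outside
  cfgc <- run_config(n_neuroblasts = 12, n_astrocytes = 4, duration = 20,
                     n_trials = 1, init_mode = "clustered")
  sc <- initialize_state(cfgc, seed = 5)
  d_soma <- sqrt((sc$neuroblasts$soma_x - 300)^2 +
                   (sc$neuroblasts$soma_y - 300)^2)
  expect_true(all(d_soma <= cfgc$cluster_radius))
  d_unit <- sqrt((sc$astrocytes$x - 300)^2 + (sc$astrocytes$y - 300)^2)
  expect_true(all(d_unit >= cfgc$cluster_radius + 28))
})

test_that("a resting-length cell alone is an equilibrium of the step", {
  p <- model_params(A_mid = 0)
  cfg <- run_config(params = p, n_neuroblasts = 1, n_astrocytes = 0,
                    duration = 10, output_interval = 10, n_trials = 1)
  st <- list(neuroblasts = nb_state(1L, c(300, 300), c(340, 300))[
               , c("cell_id", "soma_x", "soma_y", "tip_x", "tip_y", "phi_sal")],
             astrocytes = no_astro)
  tr <- simulate_trial(cfg, 1, init_state = st)
  last <- tr[tr$t_min == 10, ]
  expect_equal(last$x_um, c(300, 340), tolerance = 1e-12)
  expect_equal(last$y_um, c(300, 300), tolerance = 1e-12)
})

test_that("trials are bit-reproducible and frame counts follow the cadence", {
  cfg <- run_config(n_neuroblasts = 6, n_astrocytes = 3, duration = 120,
                    output_interval = 20, n_trials = 1, base_seed = 7,
                    amplitude_schedule = "random",
                    shrink_mode = "mismatched")
  t1 <- simulate_trial(cfg, 1)
  t2 <- simulate_trial(cfg, 1)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(length(unique(t1$t_min)), 120 / 20 + 1)
  # N_A = 0: no astrocyte rows at all
  cfg0 <- run_config(n_neuroblasts = 6, n_astrocytes = 0, duration = 60,
                     n_trials = 1)
  tr0 <- simulate_trial(cfg0, 1)
  expect_equal(sum(tr0$agent_kind == "astrocyte"), 0)
  expect_equal(length(unique(tr0$t_min)), 2)
})

test_that("the trajectory is translation-invariant modulo the field", {
  cfg <- run_config(n_neuroblasts = 4, n_astrocytes = 2, duration = 60,
                    output_interval = 20, n_trials = 1, base_seed = 11)
  st <- initialize_state(cfg, seed = 12)
  shift <- c(211.3, -97.1)
  st2 <- st
  st2$neuroblasts$soma_x <- wrap_position(cbind(st$neuroblasts$soma_x + shift[1],
                                                0), f600)[, 1]
  st2$neuroblasts$soma_y <- wrap_position(cbind(st$neuroblasts$soma_y + shift[2],
                                                0), f600)[, 1]
  st2$neuroblasts$tip_x <- wrap_position(cbind(st$neuroblasts$tip_x + shift[1],
                                               0), f600)[, 1]
  st2$neuroblasts$tip_y <- wrap_position(cbind(st$neuroblasts$tip_y + shift[2],
                                               0), f600)[, 1]
  st2$astrocytes$x <- wrap_position(cbind(st$astrocytes$x + shift[1], 0), f600)[, 1]
  st2$astrocytes$y <- wrap_position(cbind(st$astrocytes$y + shift[2], 0), f600)[, 1]
  tr1 <- simulate_trial(cfg, 1, init_state = st)
  tr2 <- simulate_trial(cfg, 1, init_state = st2)
  dx <- minimal_image(c(tr2$x_um[1], 0), c(tr1$x_um[1], 0), f600)[1]
  expect_equal(wrap_position(cbind(tr1$x_um + shift[1], 0), f600)[, 1],
               tr2$x_um, tolerance = 1e-8)
  expect_equal(wrap_position(cbind(tr1$y_um + shift[2], 0), f600)[, 1],
               tr2$y_um, tolerance = 1e-8)
})

test_that("halving dt changes the trajectory at first order only", {
  p <- model_params()
  st <- random_crowded_state(n_nb = 5, n_astro = 2, seed = 6, params = p)
  st$neuroblasts <- st$neuroblasts[, !(names(st$neuroblasts) == "l_target")]
  run_at <- function(dt) {
    cfg <- run_config(params = p, n_neuroblasts = 5, n_astrocytes = 2,
                      duration = 100, dt = dt, output_interval = 100,
                      n_trials = 1)
    tr <- simulate_trial(cfg, 1, init_state = st)
    fin <- tr[tr$t_min == 100, ]
    cbind(fin$x_um, fin$y_um)
  }
  x1 <- run_at(0.02)
  x2 <- run_at(0.01)
  x3 <- run_at(0.005)
  e1 <- max(abs(x1 - x3))
  e2 <- max(abs(x2 - x3))
  # error roughly halves with dt (first-order convergence); the e1/e3
  # comparison uses x3 as the reference
  expect_gt(e1 / e2, 1.5)
  expect_lt(max(abs(x2 - x3)), 0.5)
})

test_that("no circle ever moves further than its radius in one step", {
  cfg <- run_config(n_neuroblasts = 12, n_astrocytes = 8, duration = 300,
                    output_interval = 60, n_trials = 1, base_seed = 23)
  tr <- simulate_trial(cfg, 1)
  expect_lt(attr(tr, "max_step_disp"), 3)  # smallest circle radius r_T
})
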