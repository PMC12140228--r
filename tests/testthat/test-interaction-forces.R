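test_that("pair force law: overlap-proportional repulsion, constant adhesion", {
  apart <- circle_circle_contact(c(0, 0), 5, c(9, 0), 3, f600)
  expect_equal(pair_force(apart, H = 2.22, k_R = 10), c(0, 0))
  touch <- circle_circle_contact(c(0, 0), 5, c(7, 0), 3, f600)  # overlap 1
  expect_equal(pair_force(touch, H = 0, k_R = 10), c(-10, 0))
  # equilibrium overlap H / k_R gives zero net force
  eq <- circle_circle_contact(c(0, 0), 5, c(8 - 2.22 / 10, 0), 3, f600)
  expect_equal(sqrt(sum(pair_force(eq, H = 2.22, k_R = 10)^2)), 0,
               tolerance = 1e-12)
  # deeper overlap repels, shallower attracts
  deep <- circle_circle_contact(c(0, 0), 5, c(7, 0), 3, f600)
  expect_lt(pair_force(deep, H = 2.22, k_R = 10)[1], 0)
  shallow <- circle_circle_contact(c(0, 0), 5, c(7.9, 0), 3, f600)
  expect_gt(pair_force(shallow, H = 2.22, k_R = 10)[1], 0)
})

test_that("adhesion pairing table follows the cell-part combinations", {
  expect_true(is.na(select_adhesion("neuroblast", 1, "neuroblast", 1)))
  expect_equal(select_adhesion("neuroblast", 1, "neuroblast", 2, H_N_t = 1.11),
               1.11)
  expect_equal(select_adhesion("neuroblast", 1, "astrocyte", 3), 0)
  expect_equal(select_adhesion("astrocyte", 2, "astrocyte", 2,
                               H_A = 0.56, H_a = 22.2), 22.2)
  expect_equal(select_adhesion("astrocyte", 1, "astrocyte", 2,
                               H_A = 0.56, H_a = 22.2), 0.56)
})

test_that("inconstant adhesion schedules are clamped and mean-preserving", {
  sp <- adhesion_schedule("periodic", H_mid = 2.22, A_H = 8)
  expect_true(all(adhesion_strength(seq(0, 1500, by = 1), sp) >= 0))
  s0 <- adhesion_schedule("periodic", H_mid = 2.22, A_H = 0)
  expect_equal(adhesion_strength(c(0, 100, 333), s0), rep(2.22, 3))
  sr <- adhesion_schedule("random", H_mid = 2.22, sigma_H = 4)
  set.seed(8)
  draws <- redraw_random_adhesion(sr, 1e5)
  expect_true(all(draws >= 0 & draws <= 2 * 2.22))
  expect_equal(mean(draws), 2.22, tolerance = 0.0222)
})

test_that("via-process forces use lever-arm weights and balance exactly", {
  soma <- c(300, 300); tip <- c(340, 300)
  # midpoint contact: soma and tip each take half the reaction
  pf <- process_forces(soma, tip, c(320, 304), 3, k_R = 10, w = 2, f600)
  expect_equal(pf$s, 0.5)
  expect_equal(pf$on_soma, pf$on_tip)
  expect_equal(pf$on_other, c(0, 10))  # overlap 1, pushed away
  expect_equal(pf$on_soma + pf$on_tip + pf$on_other, c(0, 0))
  # contact at s = 0.9: tip takes 9x the soma share
  pf <- process_forces(soma, tip, c(336, 304), 3, k_R = 10, w = 2, f600)
  expect_equal(pf$s, 0.9)
  expect_equal(pf$on_tip, 9 * pf$on_soma)
  # clamped endpoint contacts are left to the circle-circle term
  pf <- process_forces(soma, tip, c(345, 300.5), 3, k_R = 10, w = 2, f600)
  expect_equal(pf$on_other, c(0, 0))
})

test_that("the assembled ledger balances and matches the compiled engine", {
  p <- model_params()
  for (seed in 1:5) {
    st <- random_crowded_state(n_nb = 8, n_astro = 4, seed = seed, params = p)
    led <- assemble_forces(st$neuroblasts, st$astrocytes, p, f600)
    expect_lt(abs(sum(led$fx)), 1e-9)
    expect_lt(abs(sum(led$fy)), 1e-9)
    cfg <- run_config(params = p, n_neuroblasts = 8, n_astrocytes = 4,
                      duration = 20, n_trials = 1)
    fc <- chainmig:::engine_forces(
      cbind(st$neuroblasts$soma_x, st$neuroblasts$soma_y,
            st$neuroblasts$tip_x, st$neuroblasts$tip_y),
      st$neuroblasts$l_target,
      st$astrocytes$x, st$astrocytes$y, st$astrocytes$radius,
      as.integer(st$astrocytes$astro_id),
      chainmig:::engine_pars(cfg), p$H_N)
    expect_lt(max(abs(cbind(led$fx, led$fy) - fc)), 1e-9)
  }
  # a 20-agent state exercises many simultaneous contacts
  st <- random_crowded_state(n_nb = 12, n_astro = 8, seed = 99, params = p)
  led <- assemble_forces(st$neuroblasts, st$astrocytes, p, f600)
  expect_lt(max(abs(c(sum(led$fx), sum(led$fy)))), 1e-9)
})

test_that("relabelling two identical agents permutes the ledger", {
  p <- model_params()
  st <- random_crowded_state(n_nb = 6, n_astro = 2, seed = 4, params = p)
  led1 <- assemble_forces(st$neuroblasts, st$astrocytes, p, f600)
  swapped <- st$neuroblasts[c(2, 1, 3:6), ]
  swapped$cell_id <- 1:6
  led2 <- assemble_forces(swapped, st$astrocytes, p, f600)
  perm <- c(3, 4, 1, 2, 5:nrow(led1))  # soma/tip rows of cells 1 and 2 swap
  expect_equal(led1$fx[perm], led2$fx, tolerance = 1e-12)
  expect_equal(led1$fy[perm], led2$fy, tolerance = 1e-12)
})

test_that("two adhesive somas relax to the stable contact depth and stay paired", {
  p <- model_params()
  # two cells side by side, axes parallel, somas overlapping slightly
  nb <- dplyr::bind_rows(
    nb_state(1L, c(300, 300), c(340, 300), phi_sal = 0),
    nb_state(2L, c(300, 307), c(340, 307), phi_sal = 0))
  nb$phi_sal <- c(0, 0)
  state <- list(neuroblasts = nb[, !(names(nb) == "l_target")],
                astrocytes = no_astro)
  p0 <- model_params(A_mid = 0)  # no saltation: watch pure contact relaxation
  cfg <- run_config(params = p0, n_neuroblasts = 2, n_astrocytes = 0,
                    duration = 60, output_interval = 10, n_trials = 1)
  tr <- simulate_trial(cfg, 1, init_state = state)
  last <- tr[tr$t_min == 60 & tr$circle_role == "soma", ]
  gap <- abs(last$y_um[2] - last$y_um[1])
  overlap <- 2 * p0$r_S - gap
  expect_equal(overlap, p0$H_N / p0$k_R, tolerance = 1e-3)
})
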