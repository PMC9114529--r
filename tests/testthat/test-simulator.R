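test_that("settings are validated", {
  expect_error(simulation_settings(dt = 0), "dt")
  expect_error(simulation_settings(t_fin = 1, dt = 0.3), "multiple")
  expect_error(simulation_settings(n_replicates = 0), "positive integer")
  s <- simulation_settings(dt = 0.01, t_fin = 12)
  expect_identical(s$n_steps, 1200L)
})

test_that("initial conditions respect the box, the seed and the mean", {
  set.seed(123)
  st <- sample_initial_state(12)
  expect_true(all(st > 0))
  expect_true(all(st[, c("N", "D", "J", "VR")] < 6000))
  expect_true(all(st[, c("I", "V")] < 600))
  # same seed twice -> identical states
  set.seed(123)
  expect_identical(sample_initial_state(12), st)
  # uniform(0, 6000) has mean 3000: check the large-sample average
  set.seed(5)
  a <- sample_initial_state(12, n_replicates = 10000)
  m <- mean(a[1, , ])                      # all N draws
  se <- 6000 / sqrt(12) / sqrt(12 * 10000) # sd of uniform / sqrt(n)
  expect_lt(abs(m - 3000), 4 * se)
})

test_that("Euler integration follows the closed form for pure decay", {
  # start with only NICD and activated VEGFR present and make every
  # production/binding term numerically negligible: both species then decay
  # as I_k = I_0 * (1 - gamma_S * dt)^k under the explicit scheme
  p <- model_parameters(N0 = 1e-12, D0 = 1e-12, J0 = 1e-12, VR0 = 1e-12,
                        k_C = 1e-30, k_T = 1e-30)
  st <- row_state(cbind(N = 0, D = 0, J = 0, I = c(500, 100),
                        VR = 0, V = c(400, 50)))
  s <- simulation_settings(dt = 0.01, t_fin = 2)
  tr <- integrate_row(st, p, pattern_layout(2, n_on = 0), s,
                      record = FALSE)
  k <- s$n_steps
  expect_equal(unname(unclass(tr$final)[, "I"]),
               c(500, 100) * (1 - p$gamma_S * s$dt)^k, tolerance = 1e-9)
  expect_equal(unname(unclass(tr$final)[, "V"]),
               c(400, 50) * (1 - p$gamma_S * s$dt)^k, tolerance = 1e-9)
})

test_that("trajectory recording is decimated and spans [0, t_fin]", {
  set.seed(2)
  tr <- integrate_row(sample_initial_state(4), default_p,
                      pattern_layout(4),
                      simulation_settings(t_fin = 3, record_every = 1))
  expect_equal(tr$time, 0:3)
  expect_identical(tr$final, tr$states[[length(tr$states)]])
  expect_true(all(diff(tr$time) > 0))
})

test_that("compiled and reference integrators agree to machine precision", {
  set.seed(31)
  init <- sample_initial_state(5)
  lay <- pattern_layout(5, n_on = 2, d_line = 3000, j_line = 1000)
  s <- simulation_settings(t_fin = 6)
  tr <- integrate_row(init, default_p, lay, s, record = FALSE)
  arr <- array(t(unclass(init)), c(6, 5, 1))
  cpp <- notchsprout:::euler_ensemble(arr, default_p, lay, s$dt, s$n_steps)
  expect_equal(t(cpp$final[, , 1]), unclass(tr$final),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a destabilizing step size raises a diagnostic, not NaNs", {
  set.seed(8)
  init <- sample_initial_state(4)
  expect_error(
    integrate_row(init, default_p, pattern_layout(4, d_line = 3000),
                  simulation_settings(dt = 5, t_fin = 100)),
    "integration failure")
})

test_that("ensembles are reproducible and seed-faithful", {
  lay <- pattern_layout(6, d_line = 3000)
  s <- simulation_settings(n_replicates = 40, seed = 77, t_fin = 2)
  e1 <- run_ensemble(default_p, lay, s)
  e2 <- run_ensemble(default_p, lay, s)
  expect_identical(e1$efcs, e2$efcs)
  expect_identical(e1$summary, e2$summary)
  e3 <- run_ensemble(default_p, lay,
                     simulation_settings(n_replicates = 40, seed = 78,
                                         t_fin = 2))
  expect_false(identical(e1$efcs, e3$efcs))
})

test_that("ensemble summaries are invariant under mask rotation", {
  # rotating the two on-line blocks around the periodic row relabels cells
  # but cannot change the ensemble statistics beyond Monte-Carlo noise
  s <- simulation_settings(n_replicates = 400, seed = 10, t_fin = 12)
  base <- pattern_layout(12, d_line = 3000)
  rot <- pattern_layout(12, on_line = rotate_vec(base$on_line, 5),
                        d_line = 3000)
  m1 <- run_ensemble(default_p, base, s, keep_final = FALSE)$summary
  m2 <- run_ensemble(default_p, rot, s, keep_final = FALSE)$summary
  expect_lt(abs(m1$efcs_mean - m2$efcs_mean), 1.5)
})

test_that("halving dt leaves the ensemble mean within Monte-Carlo error", {
  lay <- pattern_layout(12, d_line = 3000)
  e1 <- run_ensemble(default_p, lay,
                     simulation_settings(n_replicates = 200, seed = 5),
                     keep_final = FALSE)
  e2 <- run_ensemble(default_p, lay,
                     simulation_settings(dt = 0.005, n_replicates = 200,
                                         seed = 5), keep_final = FALSE)
  se <- stats::sd(e1$efcs, na.rm = TRUE) / sqrt(200)
  expect_lt(abs(e1$summary$efcs_mean - e2$summary$efcs_mean), max(se, 0.5))
})
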