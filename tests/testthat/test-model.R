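test_that("parameter constructor validates signs and completeness", {
  p <- model_parameters()
  # regulatory structure of the default set
  expect_gt(p$lambda_F_D, 1)   # Fringe strengthens Dll4-Notch1 binding
  expect_lt(p$lambda_F_J, 1)   # ... and weakens Jag1-Notch1 binding
  expect_gt(p$lambda_I_N, 1); expect_gt(p$lambda_I_J, 1)
  expect_lt(p$lambda_I_D, 1); expect_lt(p$lambda_I_VR, 1)
  expect_error(model_parameters(gamma = -1), "strictly positive")
  expect_error(model_parameters(I0 = 0), "strictly positive")
  expect_error(model_parameters(lambda_F_D = -2), ">= 0")
})

test_that("external terms average neighbours and add line ligand", {
  M <- 6
  uniform <- row_state(matrix(rep(c(100, 40, 70, 0, 0, 0), each = M), M))
  lay <- pattern_layout(M, n_on = 2, d_line = 3000, j_line = 500)
  # layout default: one on-line cell at each row end
  expect_equal(which(lay$on_line), c(1, 6))
  for (i in which(!lay$on_line)) {
    ex <- external_terms(uniform, lay, i)
    expect_equal(unname(ex), c(100, 40, 70))  # average of equal neighbours
  }
  for (i in which(lay$on_line)) {
    ex <- external_terms(uniform, lay, i)
    expect_equal(unname(ex), c(100, 40 + 3000, 70 + 500))
  }
  # periodic wrap: cell 1 of an M = 3 row neighbours cells 2 and 3
  st3 <- row_state(cbind(N = c(1, 2, 3), D = c(10, 20, 30),
                         J = c(5, 6, 7), I = 0, VR = 0, V = 0))
  ex <- external_terms(st3, pattern_layout(3, n_on = 0), 1)
  expect_equal(unname(ex["D_ext"]), (30 + 20) / 2)
  expect_error(external_terms(st3, pattern_layout(3, n_on = 0), 4),
               "out of range")
})

test_that("external terms are equivariant under cyclic rotation", {
  set.seed(7)
  M <- 8
  st <- row_state(matrix(runif(M * 6, 0, 1000), M))
  mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  lay <- pattern_layout(M, on_line = mask, d_line = 2000, j_line = 700)
  for (k in c(1, 3)) {
    st_r <- row_state(rotate_rows(unclass(st), k))
    lay_r <- pattern_layout(M, on_line = rotate_vec(mask, k),
                            d_line = 2000, j_line = 700)
    for (i in seq_len(M)) {
      j <- ((i - 1 + k) %% M) + 1
      expect_equal(external_terms(st, lay, i),
                   external_terms(st_r, lay_r, j))
    }
  }
})

test_that("rhs at the origin reduces to the production rates", {
  p <- default_p
  zero <- row_state(matrix(0, 4, 6))
  d <- row_rhs(zero, p, pattern_layout(4, n_on = 0))
  expect_equal(unname(d[, "N"]), rep(p$N0, 4))
  expect_equal(unname(d[, "D"]), rep(p$D0, 4))
  expect_equal(unname(d[, "J"]), rep(p$J0, 4))
  expect_equal(unname(d[, "VR"]), rep(p$VR0, 4))
  expect_equal(unname(d[, "I"]), rep(0, 4))
  expect_equal(unname(d[, "V"]), rep(0, 4))
})

test_that("Notch balances production against degradation when alone", {
  # no ligands anywhere and no NICD: dN/dt = N0 - gamma * N
  p <- default_p
  st <- row_state(cbind(N = c(1000, p$N0 / p$gamma), D = 0, J = 0, I = 0,
                        VR = 0, V = 0))
  d <- row_rhs(st, p, pattern_layout(2, n_on = 0))
  expect_equal(unname(d[1, "N"]), p$N0 - p$gamma * 1000)
  expect_equal(unname(d[2, "N"]), 0)
})

test_that("zero line content makes the dynamics mask-independent", {
  st <- fixed_state4()
  p <- default_p
  d0 <- row_rhs(st, p, pattern_layout(4, n_on = 0))
  d2 <- row_rhs(st, p, pattern_layout(4, n_on = 2, d_line = 0, j_line = 0))
  d4 <- row_rhs(st, p, pattern_layout(4, on_line = rep(TRUE, 4)))
  expect_identical(d0, d2)
  expect_identical(d0, d4)
})

test_that("unpatterned uniform row settles on the root-solver fixed point", {
  skip_if_not_installed("pracma")
  p <- default_p
  lay <- pattern_layout(2)
  # independent oracle: nonlinear root of the per-cell equations under
  # uniformity (each cell's neighbours equal itself)
  g <- function(x) {
    x <- as.vector(x)
    row_rhs(rbind(x, x), p, lay)[1, ]
  }
  root <- pracma::fsolve(g, c(2000, 500, 1500, 200, 400, 200))$x
  root <- as.vector(root)
  expect_lt(max(abs(g(root))), 1e-6)
  # identical cells stay identical (the symmetric subspace is invariant),
  # so a uniform start must relax onto the root-solver fixed point
  st <- row_state(rbind(root * 1.2, root * 1.2))
  tr <- integrate_row(st, p, lay, simulation_settings(t_fin = 300),
                      record = FALSE)
  expect_equal(unname(unclass(tr$final)[1, ]), root, tolerance = 1e-3)
  expect_equal(unname(unclass(tr$final)[2, ]), root, tolerance = 1e-3)
})

test_that("asymmetric long-run states are genuine fixed points", {
  # a non-uniform start relaxes onto the alternating steady state of the
  # lateral-inhibition network; polishing it with the independent root
  # solver must reproduce it (the full 12-dimensional system this time)
  skip_if_not_installed("pracma")
  p <- default_p
  lay <- pattern_layout(2)
  start <- c(2558, 239, 755, 120, 245, 245)
  st <- row_state(rbind(start * 1.05, start * 0.95))
  tr <- integrate_row(st, p, lay, simulation_settings(t_fin = 1000),
                      record = FALSE)
  expect_lt(max(abs(row_rhs(tr$final, p, lay))), 1e-8)
  g12 <- function(x) as.vector(row_rhs(matrix(as.vector(x), 2, 6), p, lay))
  polished <- pracma::fsolve(g12, as.vector(unclass(tr$final)) * 1.01)$x
  expect_equal(as.vector(unclass(tr$final)), as.vector(polished),
               tolerance = 1e-4)
})

test_that("trajectories from the initial-condition box stay in bounds", {
  p <- default_p
  lay <- pattern_layout(6, d_line = 3000, j_line = 3000)
  lambda_max <- max(1, p$lambda_I_N, p$lambda_I_D, p$lambda_I_J,
                    p$lambda_I_VR, p$lambda_V_D)
  prod_max <- max(p$N0, p$D0, p$J0, p$VR0)
  bound <- prod_max * lambda_max / min(p$gamma, p$gamma_S)
  set.seed(99)
  for (rep in 1:3) {
    tr <- integrate_row(sample_initial_state(6), p, lay,
                        simulation_settings(t_fin = 12))
    for (st in tr$states) {
      expect_true(all(st >= 0))
      expect_true(all(st[, c("N", "D", "J", "VR")] <= 6000 + bound))
      # NICD/activated VEGFR are bounded by influx/decay balance too
      expect_true(all(is.finite(st)))
    }
  }
})
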