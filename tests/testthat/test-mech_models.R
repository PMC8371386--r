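test_that("transition rates follow the exponential form and reject bad input", {
  expect_equal(transition_rate(0, 2e-3, 0.05), 2e-3)
  expect_equal(transition_rate(-40, 1, 0), 1)
  expect_equal(transition_rate(20, 2e-3, 0.05), 2e-3 * exp(1))
  expect_error(transition_rate(0, -1, 0.05), "positive")
  expect_error(rate_params(0, 0.1, 1e-3, 0.1), "positive")
  expect_error(rate_params(1e-3, NA, 1e-3, 0.1), "finite")
})

test_that("gate kinetics: rhs endpoints, steady state and time constant", {
  p <- rate_params(0.5, 0, 0.5, 0)  # alpha = beta = 0.5 at all V
  expect_equal(gate_rhs(0, 12, p), 0.5)
  expect_equal(gate_rhs(1, 12, p), -0.5)
  expect_equal(gate_steady_state(-30, p), 0.5)
  expect_equal(gate_time_constant(-30, p), 1)

  pa <- hh_default$activation
  for (V in c(-80, -40, 0, 40)) {
    xinf <- gate_steady_state(V, pa)
    expect_equal(gate_rhs(xinf, V, pa), 0, tolerance = 1e-15)
    # tau * (alpha + beta) = 1 identity
    a <- transition_rate(V, pa$A_alpha, pa$B_alpha)
    b <- transition_rate(V, pa$A_beta, pa$B_beta)
    expect_equal(gate_time_constant(V, pa) * (a + b), 1)
  }
  # hERG activation barely open at the holding potential
  expect_lt(gate_steady_state(-80, pa), 0.1)
  expect_gt(gate_steady_state(-80, pa), 0)
  # scaling both rates halves the time constant
  p2 <- rate_params(1, 0, 1, 0)
  expect_equal(gate_time_constant(0, p2), gate_time_constant(0, p) / 2)
})

test_that("Nernst potential matches its closed form and invariances", {
  expect_equal(nernst_potential(K_out = 10, K_in = 10), 0)
  # independent evaluation with R = 8.314, F = 96485 at T = 294.55 K
  expect_equal(nernst_potential(4, 110, 294.55, 1),
               1000 * 8.314 * 294.55 / 96485 * log(4 / 110),
               tolerance = 1e-12)
  expect_equal(nernst_potential(4, 110, 294.55, 1), -84.117, tolerance = 1e-4)
  expect_equal(nernst_potential(8, 220), nernst_potential(4, 110))
  expect_error(nernst_potential(K_out = 0), "positive")
})

test_that("Ohmic current is zero at the reversal potential and linear in g", {
  expect_equal(hh_current(0.5, 0.5, E_K, 1, E_K), 0)
  expect_equal(hh_current(1, 1, 10, 1, 0), 10)
  expect_equal(hh_current(0.3, 0.7, 20, 2, -80), 2 * 0.3 * 0.7 * 100)
  expect_error(hh_current(1, 1, 0, -1, 0), "positive")
})

test_that("three-state chain conserves occupancy and has a valid steady state", {
  for (V in c(-120, -80, 0, 40)) {
    s <- c(0.2, 0.5, 0.3)
    expect_equal(sum(three_state_rhs(s, V, gt_default)), 0, tolerance = 1e-15)
    ss <- three_state_steady_state(V, gt_default)
    expect_equal(sum(ss), 1, tolerance = 1e-12)
    expect_true(all(ss >= 0 & ss <= 1))
    expect_equal(three_state_rhs(ss, V, gt_default), rep(0, 3),
                 tolerance = 1e-15)
  }
  # symmetric chain: uniform stationary distribution
  sym <- three_state_model(1, k12 = c(1, 0), k21 = c(1, 0), k23 = c(1, 0),
                           k32 = c(1, 0), inactivation = hh_default$inactivation)
  expect_equal(three_state_steady_state(0, sym), rep(1 / 3, 3))
})

test_that("three-state solution matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  V <- -40
  Q <- three_state_rate_matrix(V, gt_default)
  s0 <- three_state_steady_state(-80, gt_default)
  p <- step_protocol(1000, V, holding = -80)
  tr <- integrate_gates(function(y, Vv) three_state_rhs(y, Vv, gt_default),
                        p, s0, sim_config(sample_ms = 50))
  for (i in seq_along(tr$times)) {
    oracle <- as.vector(Matrix::expm(Q * tr$times[i]) %*% s0)
    expect_equal(unname(tr$states[i, ]), oracle, tolerance = 1e-6)
  }
  # long-time integration approaches the stationary distribution
  pl <- step_protocol(60000, V, holding = -80)
  trl <- integrate_gates(function(y, Vv) three_state_rhs(y, Vv, gt_default),
                         pl, s0, sim_config(sample_ms = 60000))
  expect_equal(unname(trl$states[nrow(trl$states), ]),
               three_state_steady_state(V, gt_default), tolerance = 1e-5)
})

test_that("open-state relaxation is two-exponential, not one-exponential", {
  # deactivation tail at -40 mV starting from a high-open state
  V <- -40
  act <- step_protocol(c(1000, 1500), c(-80, 40), holding = -80)
  s_act <- simulate_states(gt_default, act, sim_config(sample_ms = 100))
  s0 <- s_act$states[nrow(s_act$states), 1:3]
  tail <- step_protocol(4000, V, holding = -80)
  tr <- integrate_gates(function(y, Vv) three_state_rhs(y, Vv, gt_default),
                        tail, s0, sim_config(sample_ms = 2))
  t <- tr$times
  o <- tr$states[, 3]
  # two relaxation rates from the generator's spectrum (independent linear
  # algebra); amplitudes then fitted linearly -> near-exact representation
  ev <- sort(Re(eigen(three_state_rate_matrix(V, gt_default))$values))
  lam <- ev[1:2]
  X2 <- cbind(1, exp(lam[1] * t), exp(lam[2] * t))
  res2 <- stats::lm.fit(X2, o)$residuals
  rel2 <- sqrt(sum(res2^2) / sum((o - mean(o))^2))
  expect_lt(rel2, 1e-6)
  # best single-exponential fit leaves structured residuals
  one_exp_rss <- function(lrate) {
    X1 <- cbind(1, exp(-exp(lrate) * t))
    sum(stats::lm.fit(X1, o)$residuals^2)
  }
  opt <- stats::optimize(one_exp_rss, c(log(1e-5), log(1)))
  rel1 <- sqrt(opt$objective / sum((o - mean(o))^2))
  expect_gt(rel1, 1e-3)
  # the two time constants are well separated at this voltage
  expect_gt(max(-1 / lam) / min(-1 / lam), 3)
})

test_that("parameter files round-trip both model classes", {
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(hh_default, path)
  m2 <- read_params_json(path)
  expect_equal(m2, hh_default)
  write_params_json(gt_default, path)
  g2 <- read_params_json(path)
  expect_equal(g2, gt_default)
})
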