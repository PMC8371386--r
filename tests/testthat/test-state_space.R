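# The state-space estimation machinery is validated against analytic
# oracles on noise-free candidate-model data: the activation and its
# derivative recovered from the current must match the closed-form gate
# trajectory.

test_that("activation recovery inverts the current map exactly on clean data", {
  p <- mini_pr3()
  cfg <- sim_config()
  tr <- simulate_current(hh_default, p, cfg, E_K)
  est <- recover_activation(tr, p, g = hh_default$g, E = E_K,
                            r_params = hh_default$inactivation)
  truth <- gate_closed_form_protocol(p, hh_default$activation, est$times)
  err <- abs(est$a - truth$value)[est$mask]
  expect_lt(max(err), 1e-6)
  # homogeneity: scaling current and conductance together changes nothing
  tr2 <- current_trace(tr$times, tr$current * 3, protocol = p)
  est2 <- recover_activation(tr2, p, g = 3 * hh_default$g, E = E_K,
                             r_params = hh_default$inactivation)
  expect_equal(est2$a, est$a)
})

test_that("samples near the reversal potential are masked as invalid", {
  p <- step_protocol(c(100, 100), c(E_K, 0), holding = E_K)
  cfg <- sim_config(holding = E_K)
  tr <- simulate_current(hh_default, p, cfg, E_K)
  est <- recover_activation(tr, p, g = 1, E = E_K,
                            r_params = hh_default$inactivation)
  expect_true(all(!est$mask[tr$times < 100]))
  expect_true(all(est$mask[tr$times >= 100]))
})

test_that("per-segment splines reproduce values and derivatives", {
  p <- short_step()
  cfg <- sim_config()
  tr <- simulate_current(hh_default, p, cfg, E_K)
  spl <- fit_segment_splines(tr, p, smoothing = 0)
  # interpolating spline reproduces the samples exactly
  expect_equal(predict_segment_splines(spl, tr$times), tr$current,
               tolerance = 1e-10)
  # derivative matches the analytic current derivative in segment interiors
  a <- gate_closed_form_protocol(p, hh_default$activation, tr$times)
  r <- gate_closed_form_protocol(p, hh_default$inactivation, tr$times)
  V <- voltage_at(p, tr$times)
  dIdt_true <- hh_default$g * (V - E_K) * (a$deriv * r$value +
                                             a$value * r$deriv)
  dIdt_est <- predict_segment_splines(spl, tr$times, deriv = 1)
  interior <- tr$times > 30 & tr$times < 470 |
    tr$times > 530 & tr$times < 1470
  scale <- max(abs(dIdt_true))
  expect_lt(max(abs(dIdt_est - dIdt_true)[interior]) / scale, 1e-3)
  # segments never share samples: spline is discontinuous at the boundary
  expect_lt(abs(predict_segment_splines(spl, 499.999) - tr$current[500]), 0.5)
})

test_that("too-few samples in a segment produce a warning, not an error", {
  p <- step_protocol(c(3, 500), c(-80, 20))
  tr <- simulate_current(hh_default, p, sim_config(), E_K)
  expect_warning(fit_segment_splines(tr, p, smoothing = 0), "skipped")
})

test_that("derivative estimation matches the gate equation on clean data", {
  cfg <- sim_config()
  for (p in list(mini_pr3(), mini_pr5())) {
    tr <- simulate_current(hh_default, p, cfg, E_K)
    est <- estimate_state_space(tr, p, g = hh_default$g, E = E_K,
                                r_params = hh_default$inactivation,
                                smoothing = 0)
    truth <- gate_closed_form_protocol(p, hh_default$activation, est$time)
    interior <- rep(TRUE, nrow(est))
    for (b in c(0, step_boundaries(p), protocol_duration(p)))
      interior <- interior & abs(est$time - b) > 25
    ok <- est$valid & interior
    expect_gt(sum(ok), 1000)
    expect_lt(max(abs(est$a - truth$value)[ok]), 1e-5)
    expect_lt(max(abs(est$dadt - gate_rhs(truth$value, est$v,
                                          hh_default$activation))[ok]), 1e-3)
    # late in long segments the system approaches steady state: dadt -> 0
    last_seg <- est$time > protocol_duration(p) - 100
    expect_lt(max(abs(est$dadt[est$valid & last_seg])), 1e-2)
  }
})

test_that("derivative estimation is invariant to joint scaling of g and I", {
  p <- mini_pr5()
  tr <- simulate_current(hh_default, p, sim_config(), E_K)
  est1 <- estimate_state_space(tr, p, g = 1, E = E_K,
                               r_params = hh_default$inactivation,
                               smoothing = 0)
  tr2 <- current_trace(tr$times, 2 * tr$current, protocol = p)
  est2 <- estimate_state_space(tr2, p, g = 2, E = E_K,
                               r_params = hh_default$inactivation,
                               smoothing = 0)
  expect_equal(est1$a, est2$a, tolerance = 1e-12)
  expect_equal(est1$dadt, est2$dadt, tolerance = 1e-12)
})

test_that("training-set scaling is O(1), invertible, and drops masked samples", {
  est <- data.frame(time = 1:3, a = c(0.5, 0.2, 0.9), v = c(-80, 20, -120),
                    dadt = c(0.02, -1e-3, 5e-4),
                    valid = c(TRUE, TRUE, FALSE))
  ts <- build_training_set(est)
  expect_equal(nrow(ts), 2)
  expect_equal(ts$a_scaled[1], 0.5)
  expect_equal(ts$v_scaled[1], -0.8)
  expect_equal(ts$dadt_scaled[1], 20)   # 0.02 ms^-1 * 1000
  un <- unscale_training(ts, ts$a_scaled, ts$v_scaled, ts$dadt_scaled)
  expect_equal(un$a, ts$a)
  expect_equal(un$v, ts$v)
  expect_equal(un$dadt, ts$dadt)
  expect_error(build_training_set(est[!est$valid, , drop = FALSE]),
               "no valid samples")
})

test_that("training sets survive a CSV round trip", {
  p <- mini_pr5()
  tr <- simulate_current(hh_default, p, sim_config(sample_ms = 10), E_K)
  est <- estimate_state_space(tr, p, g = 1, E = E_K,
                              r_params = hh_default$inactivation,
                              smoothing = 0)
  ts <- build_training_set(est)
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_set(ts, path)
  back <- read_training_set(path)
  expect_equal(back$a, ts$a, tolerance = 1e-14)
  expect_equal(back$dadt_scaled, ts$dadt_scaled, tolerance = 1e-14)
  expect_equal(attr(back, "scaling"), attr(ts, "scaling"))
})

test_that("estimation error grows with the observation noise level", {
  p <- mini_pr5()
  cfg <- sim_config()
  clean <- simulate_current(hh_default, p, cfg, E_K)
  truth <- gate_closed_form_protocol(p, hh_default$activation, clean$times)
  rmse_at_sd <- function(sd) {
    errs <- vapply(1:3, function(s) {
      noisy <- add_noise(clean, sd, seed = s)
      est <- estimate_state_space(noisy, p, g = 1, E = E_K,
                                  r_params = hh_default$inactivation,
                                  blank_ms = 5)
      ok <- est$valid & est$time > 520
      sqrt(mean((est$a - truth$value)[ok]^2))
    }, numeric(1))
    mean(errs)
  }
  r0 <- rmse_at_sd(0.02)
  r1 <- rmse_at_sd(0.1)
  r2 <- rmse_at_sd(0.3)
  expect_lt(r0, r1)
  expect_lt(r1, r2)
})
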