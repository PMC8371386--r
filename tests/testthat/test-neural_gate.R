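test_that("network forward pass matches a hand-computed example", {
  spec <- network_spec(n_inputs = 2, n_outputs = 1, hidden = 1)
  # W1 maps (x1, x2, bias) -> hidden; W2 maps (hidden, bias) -> output
  w <- list(matrix(c(1, 0, 0), 3, 1), matrix(c(1, 0), 2, 1))
  expect_equal(network_forward(c(2, 99), w, spec)[1, 1], 2)
  expect_equal(network_forward(c(-2, 99), w, spec)[1, 1], -0.02)
  # zero weights give zero output
  w0 <- lapply(w, function(m) m * 0)
  expect_equal(network_forward(c(1, 1), w0, spec)[1, 1], 0)
  # final layer is linear: scaling its weights scales the output
  w3 <- w; w3[[2]] <- 3 * w3[[2]]
  expect_equal(network_forward(c(2, 0), w3, spec)[1, 1],
               3 * network_forward(c(2, 0), w, spec)[1, 1])
  expect_error(network_forward(matrix(1, 1, 3), w, spec), "columns")
})

test_that("a zero network makes NN-d identical to the candidate gate", {
  spec <- network_spec(hidden = c(8, 8))
  model <- neural_gate_model(spec, mode = "discrepancy",
                             candidate = hh_default$activation,
                             inactivation = hh_default$inactivation,
                             seed = 3)
  model$weights <- lapply(model$weights, function(w) w * 0)
  a <- seq(-0.1, 1.1, by = 0.15)
  for (V in c(-120, -60, 0, 40))
    expect_identical(nn_discrepancy_rhs(a, V, model),
                     gate_rhs(a, V, hh_default$activation))
  # and the steady-state root matches the candidate's
  expect_equal(nn_steady_state(model, -20),
               gate_steady_state(-20, hh_default$activation),
               tolerance = 1e-8)
})

test_that("zero-network NN-d simulates exactly like the candidate model", {
  spec <- network_spec(hidden = c(8, 8))
  model <- neural_gate_model(spec, mode = "discrepancy",
                             candidate = hh_default$activation,
                             inactivation = hh_default$inactivation,
                             g = hh_default$g, seed = 3)
  model$weights <- lapply(model$weights, function(w) w * 0)
  for (p in list(short_step(), mini_pr5())) {
    ref <- simulate_current(hh_default, p, sim_config(sample_ms = 10), E_K,
                            method = "dopri5")
    nn <- simulate_current(model, p, sim_config(sample_ms = 10), E_K)
    expect_lt(max(abs(ref$current - nn$current)), 1e-5)
  }
})

test_that("rates mode is a classical gate for constant network outputs", {
  spec <- network_spec(n_inputs = 1, n_outputs = 2, hidden = 4)
  model <- neural_gate_model(spec, mode = "rates", seed = 1)
  # zero hidden weights, bias-only output: constant raw outputs (o1, o2)
  model$weights <- lapply(model$weights, function(w) w * 0)
  o <- c(0.3, -0.4)
  model$weights[[2]][nrow(model$weights[[2]]), ] <- o
  alpha <- log1p(exp(0.3)) * 1e-3
  beta <- log1p(exp(-0.4)) * 1e-3
  for (a in c(0, 0.5, 1))
    expect_equal(nn_rates_rhs(a, -50, model), alpha * (1 - a) - beta * a,
                 tolerance = 1e-12)
  expect_equal(nn_rates_rhs(0, 10, model), alpha)
  expect_equal(nn_rates_rhs(1, 10, model), -beta)
  # rhs is affine in a at fixed V
  vals <- nn_rates_rhs(c(0, 0.5, 1), -20, model)
  expect_equal(vals[2], mean(c(vals[1], vals[3])), tolerance = 1e-12)
})

test_that("mode mismatches and missing pieces are rejected", {
  spec <- network_spec(hidden = 4)
  full <- neural_gate_model(spec, mode = "full", seed = 1)
  expect_error(nn_discrepancy_rhs(0.5, 0, full), "mode")
  expect_error(nn_rates_rhs(0.5, 0, full), "mode")
  expect_error(neural_gate_model(spec, mode = "discrepancy"), "candidate")
  expect_error(neural_gate_model(network_spec(hidden = 4), mode = "rates"),
               "rates mode")
  expect_error(simulate_states(full, short_step()), "inactivation")
})

test_that("training drives a zero-target problem to a near-zero network", {
  est <- data.frame(time = seq_len(400),
                    a = rep(seq(0.1, 0.9, length.out = 20), 20),
                    v = rep(seq(-100, 20, length.out = 20), each = 20),
                    dadt = 0, valid = TRUE)
  ts <- build_training_set(est)
  nn <- train_network(ts, "full", spec = network_spec(hidden = c(16, 16)),
                      seed = 2, epochs = 300, lr = 3e-3)
  expect_lt(nn$report$final_loss, 1e-4)
  expect_lt(max(abs(nn_full_rhs(est$a, est$v, nn))), 1e-3)
})

test_that("training recovers the candidate gate surface from exact tuples", {
  grid <- expand.grid(a = seq(0, 1, length.out = 30),
                      v = seq(-120, 40, length.out = 30))
  est <- data.frame(time = seq_len(nrow(grid)), a = grid$a, v = grid$v,
                    dadt = gate_rhs(grid$a, grid$v, hh_default$activation),
                    valid = TRUE)
  ts <- build_training_set(est)
  nn <- train_network(ts, "full", spec = network_spec(hidden = rep(32, 2)),
                      seed = 4, epochs = 800, lr = 3e-3)
  rmse <- sqrt(mean((nn_full_rhs(grid$a, grid$v, nn) - est$dadt)^2))
  expect_lt(rmse, 1e-3)
  # the same data through the rates head also recovers the surface, and its
  # solutions respect the [0, 1] bounds by construction
  nnr <- train_network(ts, "rates",
                       spec = network_spec(1, 2, hidden = rep(16, 2)),
                       seed = 4, epochs = 800, lr = 3e-3)
  rmse_r <- sqrt(mean((nn_rates_rhs(grid$a, grid$v, nnr) - est$dadt)^2))
  expect_lt(rmse_r, 2e-3)
  # training is deterministic given the seed
  nn2 <- train_network(ts, "full", spec = network_spec(hidden = rep(32, 2)),
                       seed = 4, epochs = 50, lr = 3e-3)
  nn3 <- train_network(ts, "full", spec = network_spec(hidden = rep(32, 2)),
                       seed = 4, epochs = 50, lr = 3e-3)
  expect_identical(nn2$weights, nn3$weights)
})

test_that("the smoothed training loss trends downward", {
  grid <- expand.grid(a = seq(0, 1, length.out = 20),
                      v = seq(-120, 40, length.out = 20))
  est <- data.frame(time = seq_len(nrow(grid)), a = grid$a, v = grid$v,
                    dadt = gate_rhs(grid$a, grid$v, hh_default$activation),
                    valid = TRUE)
  ts <- build_training_set(est)
  nn <- train_network(ts, "full", spec = network_spec(hidden = 16),
                      seed = 1, epochs = 300, batch_size = 64, lr = 3e-3)
  loss <- nn$report$loss
  smoothed <- stats::filter(loss, rep(1 / 20, 20), sides = 1)
  smoothed <- smoothed[!is.na(smoothed)]
  # allow small optimiser noise but require an overall decreasing trend
  expect_lt(smoothed[length(smoothed)], 0.5 * smoothed[1])
  expect_true(all(diff(smoothed) < abs(smoothed[1]) * 0.05))
})

test_that("nn_steady_state honours its root-finding contract", {
  # mechanistic gate: root matches the closed form
  expect_equal(nn_steady_state(hh_default$activation, -40),
               gate_steady_state(-40, hh_default$activation),
               tolerance = 1e-8)
  # a gate whose rhs has no root in [0, 1] falls back with a warning
  spec <- network_spec(hidden = 4)
  model <- neural_gate_model(spec, mode = "full", seed = 1)
  model$weights <- lapply(model$weights, function(w) w * 0)
  model$weights[[2]][nrow(model$weights[[2]]), 1] <- 5  # constant positive rhs
  expect_warning(nn_steady_state(model, -80), "no root")
})

test_that("checkpoints round-trip to identical predictions", {
  grid <- expand.grid(a = seq(0, 1, length.out = 10),
                      v = seq(-100, 20, length.out = 10))
  est <- data.frame(time = seq_len(nrow(grid)), a = grid$a, v = grid$v,
                    dadt = gate_rhs(grid$a, grid$v, hh_default$activation),
                    valid = TRUE)
  ts <- build_training_set(est)
  nn <- train_network(ts, "discrepancy", spec = network_spec(hidden = c(8, 8)),
                      candidate = hh_default$activation, seed = 9,
                      epochs = 30, inactivation = hh_default$inactivation,
                      g = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(nn, path)
  back <- load_model(path)
  expect_identical(back$mode, "discrepancy")
  expect_equal(back$weights, nn$weights, tolerance = 0)
  expect_identical(nn_discrepancy_rhs(grid$a, grid$v, back),
                   nn_discrepancy_rhs(grid$a, grid$v, nn))
  expect_equal(back$candidate, nn$candidate)
  expect_equal(back$g, 2)
  # truncated checkpoints are rejected
  txt <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 100), trunc)
  expect_error(load_model(trunc), "checkpoint")
})
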