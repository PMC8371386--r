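# Neural gate models: a feedforward network closes the activation-gate ODE,
# either replacing the whole right-hand side (mode "full"), adding a
# discrepancy term to a mechanistic candidate gate (mode "discrepancy"), or
# producing voltage-dependent transition rates (mode "rates"). Training is
# derivative regression on state-space-estimated (a, V, da/dt) tuples --
# deliberately not backpropagation through the ODE solver, which is
# impractically slow for long voltage-clamp time series.

#' Feedforward network architecture
#'
#' Fully connected multi-layer perceptron with leaky-ReLU hidden activations
#' and a linear output layer; weight matrices include the biases. The
#' default (five hidden layers of 200 nodes) matches the reference
#' architecture; depth and width are free configuration, e.g. for CPU-budget
#' reasons smaller nets are used in the package tests.
#'
#' @param n_inputs,n_outputs input/output dimensions.
#' @param hidden integer vector of hidden layer sizes.
#' @param activation hidden activation; only `"leaky_relu"` is provided.
#' @param leak negative slope of the leaky ReLU.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(n_inputs = 2, n_outputs = 1, hidden = rep(200, 5),
                         activation = "leaky_relu", leak = 0.01) {
  if (any(hidden <= 0) || n_inputs <= 0 || n_outputs <= 0)
    stop("layer sizes must be positive")
  if (!identical(activation, "leaky_relu"))
    stop("unsupported activation: ", activation)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 hidden = as.integer(hidden),
                 activation = activation, leak = leak),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Network:", x$n_inputs, "->", paste(x$hidden, collapse = "-"), "->",
      x$n_outputs, sprintf("(leaky ReLU, slope %g)\n", x$leak))
  invisible(x)
}

.layer_sizes <- function(spec) c(spec$n_inputs, spec$hidden, spec$n_outputs)

# seeded uniform fan-in initialisation; each W is (fan_in + 1) x fan_out
# with the bias in the last row
.init_weights <- function(spec, seed) {
  sizes <- .layer_sizes(spec)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1), function(m) {
    s <- 1 / sqrt(sizes[m])
    matrix(stats::runif((sizes[m] + 1) * sizes[m + 1], -s, s),
           sizes[m] + 1, sizes[m + 1])
  })
}

.lrelu <- function(z, leak) ifelse(z > 0, z, leak * z)

#' Evaluate a feedforward network
#'
#' Computes \eqn{y = W_{M+1} \circ (h_M \circ W_M) \circ \cdots \circ
#' (h_1 \circ W_1)(x)} with component-wise activations and biases folded
#' into the weight matrices.
#'
#' @param X input matrix (n samples x `spec$n_inputs`); a vector is treated
#'   as a single sample.
#' @param weights list of weight matrices, each `(fan_in + 1) x fan_out`.
#' @param spec the [network_spec()].
#' @return Output matrix (n x `spec$n_outputs`).
#' @export
network_forward <- function(X, weights, spec) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != spec$n_inputs)
    stop("input has ", ncol(X), " columns; spec expects ", spec$n_inputs)
  H <- X
  M <- length(weights)
  for (m in seq_len(M)) {
    Z <- cbind(H, 1) %*% weights[[m]]
    H <- if (m < M) .lrelu(Z, spec$leak) else Z
  }
  H
}

# forward pass keeping pre-activations for backprop; returns list(H=..., Z=...)
.forward_cache <- function(X, weights, spec) {
  M <- length(weights)
  Hs <- vector("list", M + 1)
  Zs <- vector("list", M)
  Hs[[1]] <- X
  for (m in seq_len(M)) {
    Zs[[m]] <- cbind(Hs[[m]], 1) %*% weights[[m]]
    Hs[[m + 1]] <- if (m < M) .lrelu(Zs[[m]], spec$leak) else Zs[[m]]
  }
  list(H = Hs, Z = Zs)
}

# gradient of sum(dLdY * Y) w.r.t. every weight matrix
.backward <- function(cache, weights, spec, dLdY) {
  M <- length(weights)
  grads <- vector("list", M)
  delta <- dLdY
  for (m in rev(seq_len(M))) {
    grads[[m]] <- crossprod(cbind(cache$H[[m]], 1), delta)
    if (m > 1) {
      dH <- delta %*% t(weights[[m]][seq_len(nrow(weights[[m]]) - 1), ,
                                     drop = FALSE])
      act_grad <- ifelse(cache$Z[[m - 1]] > 0, 1, spec$leak)
      delta <- dH * act_grad
    }
  }
  grads
}

#' Construct a neural gate model
#'
#' Bundles the network with everything needed to close the gate ODE: the
#' training-set scaling constants, the model mode, the candidate gate (for
#' discrepancy mode) and, optionally, the trusted inactivation gate and
#' conductance so the model can be simulated as a full channel.
#'
#' @param spec a [network_spec()].
#' @param weights list of weight matrices (defaults to seeded random
#'   initialisation).
#' @param scaling named divisors for (a, v, dadt), as stored on a
#'   [build_training_set()] result.
#' @param mode `"full"`, `"discrepancy"` or `"rates"`.
#' @param candidate [rate_params()] of the candidate activation gate;
#'   required for discrepancy mode.
#' @param inactivation optional [rate_params()] of the trusted r-gate.
#' @param g maximal conductance (uS) for current simulation.
#' @param seed seed used for weight initialisation.
#' @return Object of class `neural_gate`.
#' @export
neural_gate_model <- function(spec, weights = NULL,
                              scaling = c(a = 1, v = 100, dadt = 1e-3),
                              mode = c("full", "discrepancy", "rates"),
                              candidate = NULL, inactivation = NULL,
                              g = 1, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "rates") {
    if (spec$n_inputs != 1 || spec$n_outputs != 2)
      stop("rates mode requires a network V -> (alpha, beta): 1 input, 2 outputs")
  } else if (spec$n_inputs != 2 || spec$n_outputs != 1) {
    stop("full/discrepancy modes require a network (a, V) -> da/dt: 2 inputs, 1 output")
  }
  if (mode == "discrepancy" && !inherits(candidate, "rate_params"))
    stop("discrepancy mode requires candidate rate_params")
  if (is.null(weights)) weights <- .init_weights(spec, seed)
  sizes <- .layer_sizes(spec)
  for (m in seq_along(weights)) {
    if (!all(dim(weights[[m]]) == c(sizes[m] + 1, sizes[m + 1])))
      stop("weight matrix ", m, " has wrong shape")
  }
  structure(list(spec = spec, weights = weights, scaling = scaling,
                 mode = mode, candidate = candidate,
                 inactivation = inactivation, g = g, seed = seed,
                 report = NULL),
            class = "neural_gate")
}

#' @export
print.neural_gate <- function(x, ...) {
  cat("Neural gate model, mode =", x$mode, "\n  ")
  print(x$spec)
  if (!is.null(x$report))
    cat("  trained:", length(x$report$loss), "epochs, final loss",
        format(x$report$final_loss, digits = 4), "\n")
  invisible(x)
}

#' Neural gate right-hand sides
#'
#' `nn_full_rhs` evaluates the purely data-driven gate
#' \eqn{da/dt = N(a, V)}; `nn_discrepancy_rhs` evaluates the hybrid gate
#' \eqn{da/dt = f(a, V) + N(a, V)} with `f` the mechanistic candidate;
#' `nn_rates_rhs` evaluates the structured variant
#' \eqn{da/dt = N_\alpha(V)(1 - a) - N_\beta(V) a} with softplus-positive
#' network rates, which confines solutions started in \[0, 1\] to \[0, 1\].
#' Inputs are scaled with the model's stored constants and the network
#' output is unscaled back to ms^-1.
#'
#' @param a activation gate value(s).
#' @param V membrane voltage(s), mV.
#' @param model a [neural_gate_model()] of the matching mode.
#' @return da/dt in ms^-1.
#' @export
nn_full_rhs <- function(a, V, model) {
  if (model$mode != "full") stop("model mode is not 'full'")
  .nn_term(a, V, model)
}

#' @rdname nn_full_rhs
#' @export
nn_discrepancy_rhs <- function(a, V, model) {
  if (model$mode != "discrepancy") stop("model mode is not 'discrepancy'")
  if (is.null(model$candidate)) stop("discrepancy model lacks candidate params")
  gate_rhs(a, V, model$candidate) + .nn_term(a, V, model)
}

#' @rdname nn_full_rhs
#' @export
nn_rates_rhs <- function(a, V, model) {
  if (model$mode != "rates") stop("model mode is not 'rates'")
  s <- model$scaling
  out <- network_forward(matrix(V / s[["v"]], ncol = 1),
                         model$weights, model$spec)
  alpha <- .softplus(out[, 1]) * s[["dadt"]]
  beta <- .softplus(out[, 2]) * s[["dadt"]]
  alpha * (1 - a) - beta * a
}

# network contribution to da/dt (scaled in, unscaled out), modes full/discrepancy
.nn_term <- function(a, V, model) {
  s <- model$scaling
  X <- cbind(a / s[["a"]], V / s[["v"]])
  network_forward(X, model$weights, model$spec)[, 1] * s[["dadt"]]
}

.softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
.sigmoid <- function(z) 1 / (1 + exp(-z))

#' The gate right-hand side of any activation model as a function
#'
#' Returns `function(a, V)` giving da/dt in ms^-1, dispatching on the model:
#' mechanistic [rate_params()] give the mass-action form, neural gates give
#' their mode's network form. Used by the simulator and root finders.
#'
#' @param model a [rate_params()] or [neural_gate_model()].
#' @return A function `(a, V) -> da/dt`.
#' @export
gate_rhs_fun <- function(model) {
  if (inherits(model, "rate_params"))
    return(function(a, V) gate_rhs(a, V, model))
  if (inherits(model, "neural_gate")) {
    return(switch(model$mode,
      full = function(a, V) nn_full_rhs(a, V, model),
      discrepancy = function(a, V) nn_discrepancy_rhs(a, V, model),
      rates = function(a, V) nn_rates_rhs(a, V, model)))
  }
  stop("no gate right-hand side for this object")
}

#' Train a neural gate by derivative regression
#'
#' Minimises the mean squared error between the (scaled) estimated
#' derivatives and the model's prediction with Adam: for mode `"full"` the
#' network regresses da/dt directly; for `"discrepancy"` it regresses the
#' residual da/dt - f(a, V) of the candidate gate; for `"rates"` the loss is
#' taken through the structured form so the network learns positive
#' transition rates. Deterministic for a given seed (weight initialisation
#' and minibatch shuffling both derive from it); the caller's RNG state is
#' preserved.
#'
#' @param ts a [build_training_set()] result.
#' @param mode `"full"`, `"discrepancy"` or `"rates"`.
#' @param spec a [network_spec()] (for `"rates"` use 1 input, 2 outputs).
#' @param candidate [rate_params()] of the candidate gate (discrepancy mode).
#' @param seed integer seed; required for reproducibility.
#' @param epochs number of passes over the data.
#' @param lr initial Adam learning rate.
#' @param lr_final learning rate in the final epoch; the rate decays
#'   geometrically from `lr` to `lr_final` across epochs (set equal to `lr`
#'   for a constant rate).
#' @param batch_size minibatch size; batches are re-shuffled every epoch.
#' @param inactivation,g optional trusted r-gate and conductance attached to
#'   the returned model so it can be simulated as a channel.
#' @return A trained [neural_gate_model()] with a `report` field holding the
#'   per-epoch loss trajectory, final loss, seed and optimiser settings.
#' @export
train_network <- function(ts, mode = c("full", "discrepancy", "rates"),
                          spec = network_spec(), candidate = NULL,
                          seed = 1, epochs = 400, lr = 3e-3,
                          lr_final = lr / 10, batch_size = Inf,
                          inactivation = NULL, g = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "training_set"))
  if (nrow(ts) == 0) stop("empty training set")
  if (mode == "discrepancy" && !inherits(candidate, "rate_params"))
    stop("discrepancy mode requires candidate rate_params")
  scaling <- attr(ts, "scaling")
  model <- neural_gate_model(spec, scaling = scaling, mode = mode,
                             candidate = candidate,
                             inactivation = inactivation, g = g, seed = seed)
  W <- model$weights
  n <- nrow(ts)
  target <- ts$dadt_scaled
  if (mode == "discrepancy")
    target <- target - gate_rhs(ts$a, ts$v, candidate) / scaling[["dadt"]]
  X <- if (mode == "rates") matrix(ts$v_scaled, ncol = 1)
       else cbind(ts$a_scaled, ts$v_scaled)
  a_raw <- ts$a

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1)

  mW <- lapply(W, function(w) w * 0)
  vW <- mW
  step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr_ep <- if (epochs > 1)
    lr * (lr_final / lr)^((seq_len(epochs) - 1) / (epochs - 1)) else lr
  losses <- numeric(epochs)
  bsz <- min(batch_size, n)
  for (ep in seq_len(epochs)) {
    ord <- if (n > bsz) sample.int(n) else seq_len(n)
    nb <- ceiling(n / bsz)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[(((bi - 1) * bsz) + 1):min(bi * bsz, n)]
      Xb <- X[idx, , drop = FALSE]
      tb <- target[idx]
      cache <- .forward_cache(Xb, W, spec)
      out <- cache$H[[length(cache$H)]]
      if (mode == "rates") {
        ab <- a_raw[idx]
        alpha <- .softplus(out[, 1]); beta <- .softplus(out[, 2])
        pred <- alpha * (1 - ab) - beta * ab
        res <- pred - tb
        loss <- mean(res^2)
        dLdY <- cbind(2 * res * (1 - ab) * .sigmoid(out[, 1]),
                      2 * res * (-ab) * .sigmoid(out[, 2])) / length(idx)
      } else {
        res <- out[, 1] - tb
        loss <- mean(res^2)
        dLdY <- matrix(2 * res / length(idx), ncol = 1)
      }
      if (!is.finite(loss))
        stop("training aborted: non-finite loss at epoch ", ep,
             " (try a smaller learning rate)")
      grads <- .backward(cache, W, spec, dLdY)
      step <- step + 1
      for (m in seq_along(W)) {
        mW[[m]] <- b1 * mW[[m]] + (1 - b1) * grads[[m]]
        vW[[m]] <- b2 * vW[[m]] + (1 - b2) * grads[[m]]^2
        mhat <- mW[[m]] / (1 - b1^step)
        vhat <- vW[[m]] / (1 - b2^step)
        W[[m]] <- W[[m]] - lr_ep[ep] * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + loss * length(idx)
    }
    losses[ep] <- ep_loss / n
  }
  model$weights <- W
  model$report <- list(loss = losses, final_loss = losses[epochs],
                       seed = seed,
                       optimiser = list(algorithm = "adam", lr = lr,
                                        lr_final = lr_final, epochs = epochs,
                                        batch_size = bsz))
  model
}

#' Steady state of a (possibly neural) activation gate at fixed voltage
#'
#' Finds a root of the gate right-hand side in \[0, 1\] by bracketing
#' bisection over a fine grid. If no sign change exists in \[0, 1\] the
#' endpoint with the smallest absolute derivative is cross-checked against a
#' 10 s simulated hold and the simulation endpoint is returned with a
#' warning (a trained network need not have an exact root).
#'
#' @param model a [neural_gate_model()] or [rate_params()].
#' @param V holding voltage (mV).
#' @return Scalar steady-state activation.
#' @export
nn_steady_state <- function(model, V) {
  f <- gate_rhs_fun(model)
  grid <- seq(0, 1, length.out = 201)
  vals <- vapply(grid, function(a) f(a, V), numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (any(vals == 0)) return(grid[which(vals == 0)[1]])
  if (length(flip)) {
    root <- stats::uniroot(function(a) f(a, V), c(grid[flip[1]],
                                                  grid[flip[1] + 1]),
                           tol = 1e-12)
    return(root$root)
  }
  # no root in [0, 1]: fall back to a long simulated hold
  warning("gate right-hand side has no root in [0, 1] at V = ", V,
          "; using a 10 s simulated hold")
  a0 <- grid[which.min(abs(vals))]
  res <- .dopri5(function(t, y) f(y, V), 0, 10000, a0, numeric(0))
  res$y_end
}

#' @export
steady_state_init.neural_gate <- function(model, V_hold) {
  if (is.null(model$inactivation))
    stop("neural gate model has no inactivation gate attached")
  c(a = nn_steady_state(model, V_hold),
    r = gate_steady_state(V_hold, model$inactivation))
}

#' @export
simulate_states.neural_gate <- function(model, protocol, cfg = sim_config(),
                                        init = NULL, method = "auto") {
  if (identical(method, "analytic"))
    stop("analytic propagation is not available for neural gate models")
  if (is.null(model$inactivation))
    stop("neural gate model has no inactivation gate attached; set",
         " model$inactivation to simulate currents")
  if (is.null(init)) init <- steady_state_init(model, cfg$holding)
  f <- gate_rhs_fun(model)
  inact <- model$inactivation
  rhs <- function(y, V) c(f(y[1], V), gate_rhs(y[2], V, inact))
  tr <- integrate_gates(rhs, protocol, init, cfg)
  colnames(tr$states) <- c("a", "r")
  tr
}

#' Save and load neural gate checkpoints
#'
#' The checkpoint is a single JSON file: a header (format version,
#' architecture, mode, scaling, seed, candidate/inactivation parameters,
#' conductance) plus the full-precision weight matrices. Round trips restore
#' bitwise-identical forward evaluations.
#'
#' @param model a [neural_gate_model()].
#' @param path file path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "neural_gate"))
  rp <- function(p) if (is.null(p)) NULL else unclass(p)
  # weights serialised as %.17g strings: exact IEEE-754 round trip, which
  # plain JSON numbers via jsonlite do not guarantee
  wts <- lapply(model$weights, function(w)
    list(dim = dim(w), data = sprintf("%.17g", as.vector(w))))
  obj <- list(format = "iongate-checkpoint", version = 1L,
              spec = unclass(model$spec), mode = model$mode,
              scaling = as.list(model$scaling),
              candidate = rp(model$candidate),
              inactivation = rp(model$inactivation),
              g = model$g, seed = model$seed,
              report = model$report,
              weights = wts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop("cannot read checkpoint: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "iongate-checkpoint") ||
      !identical(as.integer(obj$version), 1L))
    stop("not a version-1 iongate checkpoint")
  spec <- network_spec(obj$spec$n_inputs, obj$spec$n_outputs,
                       obj$spec$hidden, obj$spec$activation, obj$spec$leak)
  rp <- function(x) if (is.null(x) || !length(x)) NULL else
    rate_params(x$A_alpha, x$B_alpha, x$A_beta, x$B_beta)
  weights <- lapply(obj$weights, function(w)
    matrix(as.numeric(w$data), w$dim[1], w$dim[2]))
  model <- neural_gate_model(spec, weights = weights,
                             scaling = unlist(obj$scaling),
                             mode = obj$mode, candidate = rp(obj$candidate),
                             inactivation = rp(obj$inactivation),
                             g = obj$g, seed = obj$seed)
  model$report <- obj$report
  model
}
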