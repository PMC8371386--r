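# Dormand-Prince 5(4) adaptive Runge-Kutta with 4th-order dense output
# (Hairer's DOPRI5 coefficients). Written here because no ODE solver package
# is available in the target environment; the tableau is standard.

.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.dp_a <- list(
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.dp_e <- c(71/57600, 0, -71/16695, 71/1920, -17253/339200, 22/525, -1/40)
.dp_d <- c(-12715105075/11282082432, 0, 87487479700/32700410799,
           -10690763975/1880347072, 701980252875/199316789632,
           -1453857185/822651844, 69997945/29380423)

# Integrate dy/dt = f(t, y) over [t0, t1]; returns dense output at out_times
# (sorted, within [t0, t1]) and the end state. Errors carry the failure time.
.dopri5 <- function(f, t0, t1, y0, out_times, atol = 1e-6, rtol = 1e-8,
                    hmax = 50, max_steps = 1000000L) {
  n <- length(y0)
  nt <- length(out_times)
  yout <- matrix(NA_real_, nt, n)
  oi <- 1L
  while (oi <= nt && out_times[oi] <= t0) {
    yout[oi, ] <- y0
    oi <- oi + 1L
  }
  t <- t0
  y <- y0
  k1 <- f(t, y)
  h <- min(hmax, t1 - t0, 1)
  nsteps <- 0L
  while (t < t1) {
    if (nsteps >= max_steps)
      stop("dopri5: maximum step count exceeded at t = ", format(t))
    if (h < 1e-12 * (abs(t) + 1))
      stop("dopri5: step size underflow at t = ", format(t))
    h <- min(h, t1 - t)
    k2 <- f(t + .dp_c[2] * h, y + h * .dp_a[[1]][1] * k1)
    k3 <- f(t + .dp_c[3] * h, y + h * (.dp_a[[2]][1] * k1 + .dp_a[[2]][2] * k2))
    k4 <- f(t + .dp_c[4] * h, y + h * (.dp_a[[3]][1] * k1 + .dp_a[[3]][2] * k2 +
                                         .dp_a[[3]][3] * k3))
    k5 <- f(t + .dp_c[5] * h, y + h * (.dp_a[[4]][1] * k1 + .dp_a[[4]][2] * k2 +
                                         .dp_a[[4]][3] * k3 + .dp_a[[4]][4] * k4))
    k6 <- f(t + h, y + h * (.dp_a[[5]][1] * k1 + .dp_a[[5]][2] * k2 +
                              .dp_a[[5]][3] * k3 + .dp_a[[5]][4] * k4 +
                              .dp_a[[5]][5] * k5))
    ynew <- y + h * (.dp_a[[6]][1] * k1 + .dp_a[[6]][3] * k3 +
                       .dp_a[[6]][4] * k4 + .dp_a[[6]][5] * k5 +
                       .dp_a[[6]][6] * k6)
    k7 <- f(t + h, ynew)
    errv <- h * (.dp_e[1] * k1 + .dp_e[3] * k3 + .dp_e[4] * k4 +
                   .dp_e[5] * k5 + .dp_e[6] * k6 + .dp_e[7] * k7)
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    err <- sqrt(mean((errv / sc)^2))
    nsteps <- nsteps + 1L
    if (is.na(err)) stop("dopri5: non-finite state at t = ", format(t))
    if (err <= 1) {
      # accepted: dense output for sample times inside (t, t + h]
      tnew <- t + h
      while (oi <= nt && out_times[oi] <= tnew + 1e-12 * max(1, abs(tnew))) {
        theta <- (out_times[oi] - t) / h
        ydiff <- ynew - y
        bspl <- h * k1 - ydiff
        rcont5 <- h * (.dp_d[1] * k1 + .dp_d[3] * k3 + .dp_d[4] * k4 +
                         .dp_d[5] * k5 + .dp_d[6] * k6 + .dp_d[7] * k7)
        th1 <- 1 - theta
        yout[oi, ] <- y + theta * (ydiff + th1 * (bspl + theta *
                        ((ydiff - h * k7 - bspl) + th1 * rcont5)))
        oi <- oi + 1L
      }
      t <- tnew
      y <- ynew
      k1 <- k7  # FSAL
      h <- min(hmax, h * min(5, max(0.2, 0.9 * err^-0.2)))
    } else {
      h <- h * max(0.2, 0.9 * err^-0.2)
    }
  }
  if (oi <= nt) yout[oi:nt, ] <- rep(y, each = nt - oi + 1L)
  list(y = yout, y_end = y, nsteps = nsteps)
}

#' Simulation configuration
#'
#' Solver tolerances follow the reference setting atol = 1e-6, rtol = 1e-8
#' for the Dormand-Prince 5(4) stepper. The sampling interval defaults to
#' 1 ms (an assumption; the true acquisition rate of archived recordings may
#' differ and is configurable).
#'
#' @param atol,rtol absolute/relative solver tolerances (> 0).
#' @param sample_ms output sampling interval (ms, > 0).
#' @param holding holding voltage (mV) used for steady-state initialisation.
#' @param max_step_ms upper bound on the adaptive step (ms).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(atol = 1e-6, rtol = 1e-8, sample_ms = 1,
                       holding = -80, max_step_ms = 50) {
  if (atol <= 0 || rtol <= 0) stop("tolerances must be positive")
  if (sample_ms <= 0) stop("sampling interval must be positive")
  structure(list(atol = atol, rtol = rtol, sample_ms = sample_ms,
                 holding = holding, max_step_ms = max_step_ms),
            class = "sim_config")
}

.sample_times <- function(protocol, cfg) {
  total <- protocol_duration(protocol)
  if (total <= 0) stop("protocol has zero total duration")
  seq(0, total, by = cfg$sample_ms)
}

#' Integrate gate dynamics over a voltage protocol
#'
#' Integrates `rhs(y, V)` with the adaptive Dormand-Prince 5(4) solver. For
#' step protocols the integration is restarted at every voltage step
#' boundary, so discontinuities in V are never stepped over; for sampled
#' protocols V(t) is interpolated linearly and the maximum step is capped
#' near the waveform's sample spacing.
#'
#' @param rhs function of `(y, V)` returning dy/dt (ms^-1) for the state
#'   vector `y`.
#' @param protocol a protocol object.
#' @param init initial state vector at t = 0.
#' @param cfg a [sim_config()].
#' @return Object of class `state_trace`: list with `times` (ms), `states`
#'   (matrix, one column per state) and the protocol.
#' @export
integrate_gates <- function(rhs, protocol, init, cfg = sim_config()) {
  tout <- .sample_times(protocol, cfg)
  n <- length(init)
  out <- matrix(NA_real_, length(tout), n)
  if (inherits(protocol, "step_protocol")) {
    ends <- cumsum(protocol$durations)
    starts <- c(0, ends[-length(ends)])
    y <- init
    total <- ends[length(ends)]
    for (i in seq_along(starts)) {
      V <- protocol$voltages[i]
      f <- function(t, y) rhs(y, V)
      last <- i == length(starts)
      sel <- tout >= starts[i] - 1e-9 & (if (last) tout <= ends[i] + 1e-9
                                         else tout < ends[i] - 1e-9)
      res <- .dopri5(f, starts[i], ends[i], y, tout[sel],
                     atol = cfg$atol, rtol = cfg$rtol,
                     hmax = cfg$max_step_ms)
      out[sel, ] <- res$y
      y <- res$y_end
    }
  } else if (inherits(protocol, "sampled_protocol")) {
    Vfun <- stats::approxfun(protocol$times, protocol$voltages, rule = 2)
    f <- function(t, y) rhs(y, Vfun(t))
    hmax <- min(cfg$max_step_ms, 10 * stats::median(diff(protocol$times)))
    res <- .dopri5(f, 0, max(protocol$times), init, tout,
                   atol = cfg$atol, rtol = cfg$rtol, hmax = hmax)
    out[] <- res$y
  } else stop("not a protocol object")
  structure(list(times = tout, states = out, protocol = protocol),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat("State trace:", length(x$times), "samples,", ncol(x$states),
      "state(s), t in [", min(x$times), ",", max(x$times), "] ms\n")
  invisible(x)
}

#' Current trace container
#'
#' @param times sample times (ms), strictly increasing.
#' @param current currents (nA).
#' @param protocol the generating protocol (optional).
#' @param voltage voltages at the sample times (mV, optional; computed from
#'   the protocol when absent).
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(times, current, protocol = NULL, voltage = NULL) {
  if (length(times) != length(current))
    stop("times and current must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(current)))
    stop("times and current must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(voltage) && !is.null(protocol))
    voltage <- voltage_at(protocol, times)
  structure(list(times = as.numeric(times), current = as.numeric(current),
                 voltage = voltage, protocol = protocol),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat("Current trace:", length(x$times), "samples, t in [", min(x$times),
      ",", max(x$times), "] ms, I in [", format(min(x$current), digits = 3),
      ",", format(max(x$current), digits = 3), "] nA\n")
  invisible(x)
}

# analytic piecewise-exponential propagation of the two HH gates on a step
# protocol: exact at constant V, used as a fast path for candidate-model
# simulation and fitting
.hh_states_analytic <- function(model, protocol, cfg, init) {
  tout <- .sample_times(protocol, cfg)
  out <- matrix(NA_real_, length(tout), 2)
  ends <- cumsum(protocol$durations)
  starts <- c(0, ends[-length(ends)])
  y <- init
  for (i in seq_along(starts)) {
    V <- protocol$voltages[i]
    last <- i == length(starts)
    sel <- tout >= starts[i] - 1e-9 & (if (last) tout <= ends[i] + 1e-9
                                       else tout < ends[i] - 1e-9)
    dt <- tout[sel] - starts[i]
    ai <- gate_steady_state(V, model$activation)
    ri <- gate_steady_state(V, model$inactivation)
    ta <- gate_time_constant(V, model$activation)
    tr <- gate_time_constant(V, model$inactivation)
    out[sel, 1] <- ai + (y[1] - ai) * exp(-dt / ta)
    out[sel, 2] <- ri + (y[2] - ri) * exp(-dt / tr)
    seg <- ends[i] - starts[i]
    y <- c(ai + (y[1] - ai) * exp(-seg / ta),
           ri + (y[2] - ri) * exp(-seg / tr))
  }
  structure(list(times = tout, states = out, protocol = protocol),
            class = "state_trace")
}

#' Simulate gate states over a protocol
#'
#' Dispatches on the model class. Initial conditions default to the steady
#' state at the configured holding voltage. `method = "analytic"` uses exact
#' piecewise-exponential propagation (two-gate Hodgkin-Huxley models on step
#' protocols only); `"dopri5"` forces numerical integration; `"auto"` picks
#' the analytic path where it is exact and the solver otherwise.
#'
#' @param model an [hh_model()], [three_state_model()] or neural gate model.
#' @param protocol a protocol object.
#' @param cfg a [sim_config()].
#' @param init initial state vector; `NULL` for steady state at holding.
#' @param method `"auto"`, `"dopri5"` or `"analytic"`.
#' @return A `state_trace`. Columns: `(a, r)` for two-gate models,
#'   `(c1, c2, o, r)` for the three-state model.
#' @export
simulate_states <- function(model, protocol, cfg = sim_config(), init = NULL,
                            method = "auto") UseMethod("simulate_states")

#' @export
simulate_states.hh_model <- function(model, protocol, cfg = sim_config(),
                                     init = NULL, method = "auto") {
  if (is.null(init)) init <- steady_state_init(model, cfg$holding)
  use_analytic <- switch(method,
    auto = inherits(protocol, "step_protocol"),
    analytic = TRUE, dopri5 = FALSE,
    stop("unknown method: ", method))
  if (use_analytic) {
    if (!inherits(protocol, "step_protocol"))
      stop("analytic propagation requires a step protocol")
    tr <- .hh_states_analytic(model, protocol, cfg, init)
  } else {
    act <- model$activation; inact <- model$inactivation
    rhs <- function(y, V) c(gate_rhs(y[1], V, act), gate_rhs(y[2], V, inact))
    tr <- integrate_gates(rhs, protocol, init, cfg)
  }
  colnames(tr$states) <- c("a", "r")
  tr
}

#' @export
simulate_states.three_state_model <- function(model, protocol,
                                              cfg = sim_config(),
                                              init = NULL, method = "auto") {
  if (is.null(init)) init <- steady_state_init(model, cfg$holding)
  if (identical(method, "analytic"))
    stop("analytic propagation is not implemented for three-state models")
  inact <- model$inactivation
  rhs <- function(y, V)
    c(three_state_rhs(y[1:3], V, model), gate_rhs(y[4], V, inact))
  tr <- integrate_gates(rhs, protocol, init, cfg)
  colnames(tr$states) <- c("c1", "c2", "o", "r")
  tr
}

#' Simulate the macroscopic current over a protocol
#'
#' Simulates all gates from the steady state at the holding voltage (unless
#' `init` is given) and applies the Ohmic map \eqn{I = g a r (V - E)}, with
#' the open-state occupancy playing the role of `a` for the three-state
#' model.
#'
#' @inheritParams simulate_states
#' @param E reversal potential (mV); defaults to [nernst_potential()] with
#'   the package's potassium defaults.
#' @return A [current_trace()].
#' @export
simulate_current <- function(model, protocol, cfg = sim_config(),
                             E = nernst_potential(), init = NULL,
                             method = "auto") {
  tr <- simulate_states(model, protocol, cfg, init = init, method = method)
  a <- if ("o" %in% colnames(tr$states)) tr$states[, "o"] else tr$states[, "a"]
  r <- tr$states[, "r"]
  V <- voltage_at(protocol, tr$times)
  current_trace(tr$times, hh_current(a, r, V, model$g, E),
                protocol = protocol, voltage = V)
}

#' Steady-state initial conditions at a holding voltage
#'
#' Analytic steady states for mechanistic models; for neural gate models the
#' activation steady state is found by root bracketing of the trained
#' right-hand side (see [nn_steady_state()]).
#'
#' @param model a model object.
#' @param V_hold holding voltage (mV).
#' @return Named state vector.
#' @export
steady_state_init <- function(model, V_hold) UseMethod("steady_state_init")

#' @export
steady_state_init.hh_model <- function(model, V_hold) {
  c(a = gate_steady_state(V_hold, model$activation),
    r = gate_steady_state(V_hold, model$inactivation))
}

#' @export
steady_state_init.three_state_model <- function(model, V_hold) {
  s <- three_state_steady_state(V_hold, model)
  c(c1 = s[1], c2 = s[2], o = s[3],
    r = gate_steady_state(V_hold, model$inactivation))
}

#' Add i.i.d. Gaussian observation noise to a current trace
#'
#' Noise is applied to the observed current only, never to the underlying
#' states. Reproducible for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param trace a [current_trace()].
#' @param sd noise standard deviation (nA), >= 0.
#' @param seed integer seed, or `NULL` to use (and advance) the session RNG.
#' @return A new [current_trace()].
#' @export
add_noise <- function(trace, sd, seed = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  if (!is.finite(sd) || sd < 0) stop("noise sd must be non-negative")
  if (sd == 0) return(trace)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  current_trace(trace$times,
                trace$current + stats::rnorm(length(trace$current), 0, sd),
                protocol = trace$protocol, voltage = trace$voltage)
}

#' Capacitance-artifact mask
#'
#' Real voltage-clamp recordings show capacitive charging transients after
#' each voltage step; the convention adopted here blanks the first 5 ms after
#' every discontinuity. Returns `TRUE` for samples to keep and `FALSE` for
#' samples with `t` in `[t_step, t_step + blank_ms)` for any step boundary.
#'
#' @param trace a [current_trace()] or a numeric vector of times (ms).
#' @param protocol the protocol whose boundaries define the blanking windows.
#' @param blank_ms blanking window length (ms), >= 0; default 5.
#' @return Logical vector, one element per sample.
#' @export
capacitance_mask <- function(trace, protocol, blank_ms = 5) {
  if (blank_ms < 0) stop("blank_ms must be non-negative")
  times <- if (inherits(trace, "current_trace")) trace$times else trace
  keep <- rep(TRUE, length(times))
  if (blank_ms == 0 || !inherits(protocol, "step_protocol")) return(keep)
  for (b in step_boundaries(protocol))
    keep <- keep & !(times >= b - 1e-9 & times < b + blank_ms - 1e-9)
  keep
}

#' Read and write current traces as CSV
#'
#' Columns `time_ms,voltage_mV,current_nA`; round trips preserve values.
#'
#' @param trace a [current_trace()].
#' @param path file path.
#' @param protocol optional protocol to attach on read.
#' @return `read_trace_csv` returns a [current_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  V <- trace$voltage
  if (is.null(V)) V <- rep(NA_real_, length(trace$times))
  df <- data.frame(time_ms = trace$times, voltage_mV = V,
                   current_nA = trace$current)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, protocol = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "voltage_mV", "current_nA")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  current_trace(df$time_ms, df$current_nA, protocol = protocol,
                voltage = df$voltage_mV)
}
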