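# Shared fixtures: default models, reversal potential, and short protocols
# sized for fast unit tests.

hh_default <- candidate_hh_params()
gt_default <- ground_truth_params()
E_K <- nernst_potential()

# a short two-step protocol: hold then depolarise
short_step <- function() step_protocol(c(500, 1000), c(-80, 20))

# miniature activation/deactivation pair for pipeline tests
mini_pr3 <- function() make_activation_protocol(
  test_voltages = c(-40, 0, 40), hold_ms = 500, test_ms = 2000,
  tail_ms = 1000)
mini_pr5 <- function() make_deactivation_protocol(
  tail_voltages = c(-120, -80, -40), hold_ms = 500, act_ms = 1500,
  tail_ms = 2000)

# closed-form HH gate solution at constant V (independent oracle)
gate_closed_form <- function(t, x0, V, p) {
  xi <- gate_steady_state(V, p)
  tau <- gate_time_constant(V, p)
  xi + (x0 - xi) * exp(-t / tau)
}

# closed-form gate value and derivative chained over the segments of a step
# protocol (independent oracle for the estimation pipeline)
gate_closed_form_protocol <- function(protocol, p, times) {
  ends <- cumsum(protocol$durations)
  starts <- c(0, ends[-length(ends)])
  x <- gate_steady_state(protocol$holding, p)
  val <- numeric(length(times))
  der <- numeric(length(times))
  for (i in seq_along(starts)) {
    V <- protocol$voltages[i]
    xi <- gate_steady_state(V, p)
    tau <- gate_time_constant(V, p)
    last <- i == length(starts)
    sel <- times >= starts[i] - 1e-9 &
      (if (last) times <= ends[i] + 1e-9 else times < ends[i] - 1e-9)
    dt <- times[sel] - starts[i]
    val[sel] <- xi + (x - xi) * exp(-dt / tau)
    der[sel] <- -(x - xi) / tau * exp(-dt / tau)
    x <- xi + (x - xi) * exp(-(ends[i] - starts[i]) / tau)
  }
  list(value = val, deriv = der)
}

# subsample a training set deterministically (test-local helper)
ts_subsample <- function(ts, n, seed = 1) {
  if (n >= nrow(ts)) return(ts)
  set.seed(seed)
  idx <- sort(sample.int(nrow(ts), n))
  out <- ts[idx, ]
  attr(out, "scaling") <- attr(ts, "scaling")
  class(out) <- class(ts)
  out
}
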