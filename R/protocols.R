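#' Voltage-clamp protocols
#'
#' A `step_protocol` is an ordered list of constant-voltage segments
#' (duration in ms, voltage in mV) preceded by an indefinite holding period;
#' a `sampled_protocol` is an arbitrary waveform given by sampled time points
#' and voltages, interpolated linearly. Both are controls V(t) for the gate
#' ODEs.
#'
#' Segment convention is half-open \[start, end): the voltage at a step
#' discontinuity belongs to the new step. This convention is shared by
#' [voltage_at()], [step_boundaries()] and the simulator, so boundary samples
#' are never double-counted.
#'
#' @param durations segment durations (ms), all positive.
#' @param voltages segment voltages (mV), finite, same length as `durations`.
#' @param holding holding voltage (mV) applied before the protocol starts;
#'   used for steady-state initial conditions.
#' @return An object of class `step_protocol` or `sampled_protocol`.
#' @export
step_protocol <- function(durations, voltages, holding = -80) {
  if (length(durations) != length(voltages) || length(durations) == 0)
    stop("durations and voltages must be non-empty and of equal length")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("all segment durations must be positive and finite")
  if (any(!is.finite(voltages)) || !is.finite(holding))
    stop("all voltages must be finite")
  structure(list(durations = as.numeric(durations),
                 voltages = as.numeric(voltages),
                 holding = as.numeric(holding)),
            class = "step_protocol")
}

#' @rdname step_protocol
#' @param times strictly increasing sample times (ms), starting at 0.
#' @export
sampled_protocol <- function(times, voltages, holding = -80) {
  if (length(times) != length(voltages) || length(times) < 2)
    stop("times and voltages must have equal length >= 2")
  if (any(!is.finite(times)) || any(!is.finite(voltages)))
    stop("times and voltages must be finite")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), voltages = as.numeric(voltages),
                 holding = as.numeric(holding)),
            class = "sampled_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat("Step protocol:", length(x$durations), "segments,",
      format(sum(x$durations)), "ms total, holding", x$holding, "mV\n")
  invisible(x)
}

#' @export
print.sampled_protocol <- function(x, ...) {
  cat("Sampled protocol:", length(x$times), "samples over",
      format(max(x$times) - min(x$times)), "ms, holding", x$holding, "mV\n")
  invisible(x)
}

#' Total duration of a protocol (ms)
#' @param p a protocol object.
#' @export
protocol_duration <- function(p) {
  if (inherits(p, "step_protocol")) sum(p$durations)
  else if (inherits(p, "sampled_protocol")) max(p$times)
  else stop("not a protocol object")
}

#' Voltage at a given time
#'
#' Step protocols use the half-open segment convention (the voltage at a
#' discontinuity is that of the new segment); sampled protocols interpolate
#' linearly. `t` may be a vector. Times outside \[0, duration\] are an error,
#' except that `t == duration` returns the final voltage.
#'
#' @param p a protocol object.
#' @param t time(s) in ms.
#' @return Voltage(s) in mV.
#' @export
voltage_at <- function(p, t) UseMethod("voltage_at")

#' @export
voltage_at.step_protocol <- function(p, t) {
  total <- sum(p$durations)
  if (any(t < 0 | t > total))
    stop("time outside protocol range [0, ", total, "]")
  starts <- cumsum(c(0, p$durations[-length(p$durations)]))
  idx <- findInterval(t, starts)
  idx[t >= total] <- length(p$durations)
  p$voltages[idx]
}

#' @export
voltage_at.sampled_protocol <- function(p, t) {
  if (any(t < min(p$times) | t > max(p$times)))
    stop("time outside protocol range [", min(p$times), ", ",
         max(p$times), "]")
  stats::approx(p$times, p$voltages, xout = t, method = "linear")$y
}

#' Times of voltage step discontinuities
#'
#' Cumulative segment start times excluding t = 0; these are the restart
#' points for the adaptive solver, the breakpoints for per-step spline
#' fitting, and the origins of capacitance blanking windows.
#'
#' @param p a [step_protocol()].
#' @return Sorted numeric vector of boundary times (ms); empty for a
#'   single-segment protocol.
#' @export
step_boundaries <- function(p) {
  stopifnot(inherits(p, "step_protocol"))
  n <- length(p$durations)
  if (n == 1) return(numeric(0))
  cumsum(p$durations)[-n]
}

#' Surrogate activation ("Pr3-like") protocol
#'
#' Repeated units of holding step, long depolarising test step, and a
#' deactivating tail step, sweeping the test voltage. Probes the activation
#' branch of (a, V) state space: long test steps let the slow activation gate
#' approach its steady state across the swept voltages. The exact waveforms
#' of the published activation protocol are not redistributable here, so this
#' is a parameterised surrogate covering the same state-space region; the
#' genuine waveform can be loaded with [read_protocol_csv()].
#'
#' @param test_voltages swept test voltages (mV).
#' @param holding holding voltage (mV).
#' @param hold_ms,test_ms,tail_ms durations of the three steps per sweep (ms).
#' @param tail_voltage voltage of the post-test deactivating step (mV).
#' @return A [step_protocol()] with `3 * length(test_voltages)` segments.
#' @export
make_activation_protocol <- function(test_voltages = seq(-60, 40, by = 20),
                                     holding = -80, hold_ms = 1000,
                                     test_ms = 4000, tail_ms = 1500,
                                     tail_voltage = -40) {
  if (length(test_voltages) == 0) stop("test_voltages must be non-empty")
  step_protocol(
    durations = rep(c(hold_ms, test_ms, tail_ms), length(test_voltages)),
    voltages = as.vector(rbind(holding, test_voltages, tail_voltage)),
    holding = holding)
}

#' @rdname make_activation_protocol
#' @export
pr3_like <- make_activation_protocol

#' Surrogate deactivation ("Pr5-like") protocol
#'
#' A fixed strong activation step followed by long swept tail steps at
#' hyperpolarised voltages: the activation gate is driven high and then
#' relaxes at each tail voltage, covering the high-a/low-V deactivation
#' branch of state space that the activation protocol does not reach.
#'
#' @param tail_voltages swept tail voltages (mV).
#' @param holding holding voltage (mV).
#' @param hold_ms,act_ms,tail_ms durations of the three steps per sweep (ms).
#' @param act_voltage voltage of the fixed activating step (mV).
#' @return A [step_protocol()].
#' @export
make_deactivation_protocol <- function(tail_voltages = seq(-120, -40, by = 20),
                                       holding = -80, hold_ms = 1000,
                                       act_ms = 2000, act_voltage = 40,
                                       tail_ms = 4000) {
  if (length(tail_voltages) == 0) stop("tail_voltages must be non-empty")
  step_protocol(
    durations = rep(c(hold_ms, act_ms, tail_ms), length(tail_voltages)),
    voltages = as.vector(rbind(holding, act_voltage, tail_voltages)),
    holding = holding)
}

#' @rdname make_deactivation_protocol
#' @export
pr5_like <- make_deactivation_protocol

#' Surrogate inactivation ("Pr4-like") protocol
#'
#' Strong long activating steps followed by brief test steps across a wide
#' voltage range (probing the fast inactivation gate), returning to holding
#' where a large slow deactivation tail develops. Used as the unseen
#' prediction protocol in the synthetic studies; together with the activation
#' protocol it leaves the sustained high-a/low-V region unexplored, which is
#' what makes it an instructive (bad) training companion for a neural gate.
#'
#' @param test_voltages swept brief test voltages (mV).
#' @param holding holding voltage (mV).
#' @param hold_ms,act_ms,test_ms durations per sweep (ms).
#' @param act_voltage fixed activating voltage (mV).
#' @return A [step_protocol()].
#' @export
make_inactivation_protocol <- function(test_voltages = seq(-120, 0, by = 20),
                                       holding = -80, hold_ms = 1000,
                                       act_ms = 800, act_voltage = 40,
                                       test_ms = 100) {
  if (length(test_voltages) == 0) stop("test_voltages must be non-empty")
  step_protocol(
    durations = rep(c(hold_ms, act_ms, test_ms), length(test_voltages)),
    voltages = as.vector(rbind(holding, act_voltage, test_voltages)),
    holding = holding)
}

#' @rdname make_inactivation_protocol
#' @export
pr4_like <- make_inactivation_protocol

#' Surrogate condensed waveform protocols
#'
#' `make_sinusoidal_protocol` emulates a condensed "sinusoidal" design: a
#' brief activating step followed by a sum of three sinusoids around -30 mV.
#' `make_ap_protocol` emulates a train of action-potential-like waveforms
#' (fast upstroke, exponential repolarisation, diastolic interval) with
#' varying peaks and durations. Both are [sampled_protocol()]s and serve as
#' unseen prediction protocols.
#'
#' @param duration_ms total duration (ms).
#' @param dt_ms sample spacing (ms).
#' @param holding holding voltage (mV).
#' @return A [sampled_protocol()].
#' @export
make_sinusoidal_protocol <- function(duration_ms = 8000, dt_ms = 1,
                                     holding = -80) {
  t <- seq(0, duration_ms, by = dt_ms)
  V <- -30 + 54 * sin(2 * pi * t / 5000) + 26 * sin(2 * pi * t / 1100) +
    10 * sin(2 * pi * t / 270)
  # leading hold and step to engage the channel, as condensed designs do
  V[t < 250] <- holding
  V[t >= 250 & t < 500] <- 20
  V <- pmin(pmax(V, -120), 60)
  sampled_protocol(t, V, holding = holding)
}

#' @rdname make_sinusoidal_protocol
#' @param n_aps number of action-potential waveforms.
#' @export
make_ap_protocol <- function(n_aps = 5, dt_ms = 1, holding = -80) {
  peak <- seq(40, 20, length.out = n_aps)
  apd <- seq(250, 450, length.out = n_aps)   # repolarisation time scale
  gap <- 600
  pieces <- lapply(seq_len(n_aps), function(i) {
    tt <- seq(0, apd[i] + gap, by = dt_ms)
    v <- ifelse(tt < 2, holding + (peak[i] - holding) * tt / 2,
                holding + (peak[i] - holding) * exp(-(tt - 2) / (apd[i] / 3)))
    v[tt > apd[i] + 100] <- holding
    v
  })
  V <- c(rep(holding, 250 / dt_ms), unlist(pieces))
  t <- seq(0, by = dt_ms, length.out = length(V))
  sampled_protocol(t, V, holding = holding)
}

#' Read and write protocols as CSV
#'
#' Step protocols use columns `duration_ms,voltage_mV`; sampled protocols use
#' `time_ms,voltage_mV`. Comma-separated, header row, UTF-8, '.' decimal.
#' The holding voltage is stored in a `# holding_mV:` comment line.
#'
#' @param p a protocol object.
#' @param path file path.
#' @return `read_protocol_csv` returns the protocol; round trips are exact.
#' @export
write_protocol_csv <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# holding_mV: %.17g", p$holding), con)
  if (inherits(p, "step_protocol")) {
    df <- data.frame(duration_ms = p$durations, voltage_mV = p$voltages)
  } else if (inherits(p, "sampled_protocol")) {
    df <- data.frame(time_ms = p$times, voltage_mV = p$voltages)
  } else stop("not a protocol object")
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path) {
  lines <- readLines(path)
  holding <- -80
  hm <- grep("^# *holding_mV:", lines)
  if (length(hm))
    holding <- as.numeric(sub("^# *holding_mV: *", "", lines[hm[1]]))
  df <- utils::read.csv(text = lines, comment.char = "#")
  if (all(c("duration_ms", "voltage_mV") %in% names(df))) {
    bad <- which(!is.finite(df$duration_ms) | df$duration_ms <= 0)
    if (length(bad))
      stop("invalid duration at data row ", bad[1])
    step_protocol(df$duration_ms, df$voltage_mV, holding = holding)
  } else if (all(c("time_ms", "voltage_mV") %in% names(df))) {
    bad <- which(c(FALSE, diff(df$time_ms) <= 0))
    if (length(bad))
      stop("non-increasing time stamp at data row ", bad[1])
    sampled_protocol(df$time_ms, df$voltage_mV, holding = holding)
  } else {
    stop("unrecognised protocol CSV header: need duration_ms or time_ms ",
         "plus voltage_mV")
  }
}
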