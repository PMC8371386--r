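# State-space estimation: recover the activation gate and its time
# derivative from a measured current trace, producing (a, V, da/dt) tuples
# for derivative-regression training of neural gate models.

# analytic value and derivative of a single HH gate along a step protocol,
# evaluated at arbitrary times (the inactivation gate is trusted, so its
# trajectory is computed from its model, not estimated from data)
.gate_along_protocol <- function(p, protocol, times, holding = NULL) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (is.null(holding)) holding <- protocol$holding
  x <- gate_steady_state(holding, p)
  ends <- cumsum(protocol$durations)
  starts <- c(0, ends[-length(ends)])
  val <- numeric(length(times))
  der <- numeric(length(times))
  for (i in seq_along(starts)) {
    V <- protocol$voltages[i]
    last <- i == length(starts)
    sel <- times >= starts[i] - 1e-9 & (if (last) times <= ends[i] + 1e-9
                                        else times < ends[i] - 1e-9)
    xi <- gate_steady_state(V, p)
    tau <- gate_time_constant(V, p)
    dt <- times[sel] - starts[i]
    val[sel] <- xi + (x - xi) * exp(-dt / tau)
    der[sel] <- -(x - xi) / tau * exp(-dt / tau)
    x <- xi + (x - xi) * exp(-(ends[i] - starts[i]) / tau)
  }
  list(value = val, deriv = der)
}

#' Recover the activation gate from a current trace
#'
#' Algebraic inversion of the Ohmic current expression: with the
#' inactivation gate r(t) computed from its trusted model, the activation is
#' estimated pointwise as \eqn{a = I / (g\,r\,(V - E))}. The denominator can
#' come arbitrarily close to zero, so samples with \eqn{|V - E| <} `v_min`
#' or \eqn{r <} `r_min` are flagged invalid rather than returned; estimates
#' are never clipped to \[0, 1\].
#'
#' @param trace a [current_trace()] (raw, or smoothed via
#'   [fit_segment_splines()] upstream).
#' @param protocol the [step_protocol()] the trace was recorded under.
#' @param g maximal conductance (uS), positive.
#' @param E reversal potential (mV).
#' @param r_params [rate_params()] of the trusted inactivation gate.
#' @param v_min,r_min singularity guards on the driving force (mV) and the
#'   inactivation open probability.
#' @return Object of class `gate_estimate`: list with `times`, `a`, `mask`
#'   (TRUE where valid), plus the inactivation trajectory `r`, its derivative
#'   `drdt`, and `V` used downstream.
#' @export
recover_activation <- function(trace, protocol, g, E, r_params,
                               v_min = 1, r_min = 1e-3) {
  stopifnot(inherits(trace, "current_trace"))
  if (g <= 0) stop("conductance g must be positive")
  V <- voltage_at(protocol, trace$times)
  rg <- .gate_along_protocol(r_params, protocol, trace$times)
  denom <- g * rg$value * (V - E)
  mask <- abs(V - E) >= v_min & rg$value >= r_min & is.finite(trace$current)
  a <- trace$current / denom
  a[!mask] <- NA_real_
  structure(list(times = trace$times, a = a, mask = mask,
                 r = rg$value, drdt = rg$deriv, V = V),
            class = "gate_estimate")
}

#' @export
print.gate_estimate <- function(x, ...) {
  cat("Gate estimate:", length(x$times), "samples,", sum(x$mask),
      "valid; a in [", format(min(x$a, na.rm = TRUE), digits = 3), ",",
      format(max(x$a, na.rm = TRUE), digits = 3), "]\n")
  invisible(x)
}

#' Per-step smoothing splines of a current trace
#'
#' Fits one cubic spline per constant-voltage segment, so the spline never
#' crosses a step discontinuity in the driving force. `smoothing = NULL`
#' selects the smoothing parameter per segment by generalised
#' cross-validation ([stats::smooth.spline]); `smoothing = 0` gives an
#' interpolating natural cubic spline (for noise-free data); any other
#' number is passed through as `spar`. Samples inside capacitance blanking
#' windows are excluded from the fit. Segments with fewer than 5 usable
#' samples are skipped with a warning.
#'
#' @param trace a [current_trace()].
#' @param protocol the [step_protocol()] defining the segments.
#' @param smoothing `NULL` (GCV), `0` (interpolation) or a `spar` value.
#' @param blank_ms capacitance blanking window (ms) after each step.
#' @return Object of class `segment_splines`.
#' @export
fit_segment_splines <- function(trace, protocol, smoothing = NULL,
                                blank_ms = 0) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(protocol, "step_protocol"))
  keep <- capacitance_mask(trace, protocol, blank_ms)
  ends <- cumsum(protocol$durations)
  starts <- c(0, ends[-length(ends)])
  segs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    last <- i == length(starts)
    sel <- trace$times >= starts[i] - 1e-9 &
      (if (last) trace$times <= ends[i] + 1e-9
       else trace$times < ends[i] - 1e-9) & keep
    tt <- trace$times[sel]
    yy <- trace$current[sel]
    if (length(tt) < 5) {
      warning("segment ", i, " skipped: only ", length(tt),
              " usable samples")
      next
    }
    if (!is.null(smoothing) && smoothing == 0) {
      segs[[i]] <- local({
        fn <- stats::splinefun(tt, yy, method = "natural")
        list(start = starts[i], end = ends[i],
             value = fn, deriv = function(t) fn(t, deriv = 1))
      })
    } else {
      ss <- if (is.null(smoothing))
        stats::smooth.spline(tt, yy, cv = FALSE)
      else stats::smooth.spline(tt, yy, spar = smoothing)
      segs[[i]] <- local({
        ss_i <- ss
        list(start = starts[i], end = ends[i],
             value = function(t) stats::predict(ss_i, t)$y,
             deriv = function(t) stats::predict(ss_i, t, deriv = 1)$y)
      })
    }
  }
  structure(list(segments = segs, protocol = protocol), class = "segment_splines")
}

#' Evaluate segment splines (value or first derivative)
#'
#' @param splines a `segment_splines` object.
#' @param times times (ms); each is mapped to its own segment under the
#'   half-open convention. Returns `NA` for times in skipped segments.
#' @param deriv 0 for the smoothed value, 1 for the first derivative.
#' @return Numeric vector.
#' @export
predict_segment_splines <- function(splines, times, deriv = 0) {
  out <- rep(NA_real_, length(times))
  for (seg in splines$segments) {
    if (is.null(seg)) next
    last <- abs(seg$end - protocol_duration(splines$protocol)) < 1e-9
    sel <- times >= seg$start - 1e-9 & (if (last) times <= seg$end + 1e-9
                                        else times < seg$end - 1e-9)
    if (!any(sel)) next
    out[sel] <- if (deriv == 0) seg$value(times[sel]) else seg$deriv(times[sel])
  }
  out
}

#' Estimate the activation derivative from current derivatives
#'
#' On a constant-voltage segment (dV/dt = 0) the product rule applied to
#' \eqn{I = g\,a\,r\,(V-E)} gives
#' \eqn{da/dt = \frac{1}{r}\left[\frac{dI/dt}{g (V-E)} - a\,dr/dt\right]},
#' which turns a spline estimate of dI/dt into a derivative estimate for the
#' activation gate. Invalid samples of the gate estimate propagate as `NA`.
#'
#' @param est a [recover_activation()] result.
#' @param dIdt spline-estimated current derivative at `est$times` (nA/ms).
#' @param g maximal conductance (uS).
#' @param E reversal potential (mV).
#' @return Numeric vector of da/dt (ms^-1), `NA` where invalid.
#' @export
estimate_activation_derivative <- function(est, dIdt, g, E) {
  stopifnot(inherits(est, "gate_estimate"))
  dadt <- (dIdt / (g * (est$V - E)) - est$a * est$drdt) / est$r
  dadt[!est$mask | !is.finite(dadt)] <- NA_real_
  dadt
}

#' Full state-space estimation pipeline for one trace
#'
#' Fits per-segment smoothing splines to the current, recovers the
#' activation from the smoothed current, and estimates its derivative from
#' the spline's derivative. This is the complete procedure turning one
#' voltage-clamp recording into (a, V, da/dt) samples.
#'
#' @inheritParams recover_activation
#' @inheritParams fit_segment_splines
#' @return A data frame with columns `time`, `a`, `v`, `dadt`, `valid`.
#' @export
estimate_state_space <- function(trace, protocol, g, E, r_params,
                                 smoothing = NULL, blank_ms = 0,
                                 v_min = 1, r_min = 1e-3) {
  spl <- fit_segment_splines(trace, protocol, smoothing = smoothing,
                             blank_ms = blank_ms)
  I_s <- predict_segment_splines(spl, trace$times, deriv = 0)
  dIdt <- predict_segment_splines(spl, trace$times, deriv = 1)
  smooth_trace <- current_trace(trace$times,
                                ifelse(is.finite(I_s), I_s, 0),
                                protocol = protocol)
  est <- recover_activation(smooth_trace, protocol, g, E, r_params,
                            v_min = v_min, r_min = r_min)
  est$mask <- est$mask & is.finite(I_s) & is.finite(dIdt) &
    capacitance_mask(trace$times, protocol, blank_ms)
  est$a[!est$mask] <- NA_real_
  dadt <- estimate_activation_derivative(est, dIdt, g, E)
  data.frame(time = est$times, a = est$a, v = est$V, dadt = dadt,
             valid = est$mask & is.finite(dadt))
}

#' Assemble a scaled training set from state-space estimates
#'
#' Concatenates estimates from one or more protocols, drops masked samples,
#' and applies the fixed scaling normalisation: `a` unchanged, `V` divided
#' by 100, `da/dt` multiplied by 1000, so each variable is O(1). The scaling
#' constants are stored with the set for inversion during simulation.
#'
#' @param estimates a data frame from [estimate_state_space()] or a list of
#'   them.
#' @param scaling named divisors applied as `x_scaled = x / scaling[...]`.
#' @return Object of class `training_set`: a data frame with raw and scaled
#'   columns and a `scaling` attribute.
#' @export
build_training_set <- function(estimates,
                               scaling = c(a = 1, v = 100, dadt = 1e-3)) {
  if (is.data.frame(estimates)) estimates <- list(estimates)
  df <- do.call(rbind, lapply(estimates, function(e)
    e[e$valid, c("a", "v", "dadt")]))
  if (is.null(df) || nrow(df) == 0)
    stop("no valid samples to build a training set from")
  rownames(df) <- NULL
  df$a_scaled <- df$a / scaling[["a"]]
  df$v_scaled <- df$v / scaling[["v"]]
  df$dadt_scaled <- df$dadt / scaling[["dadt"]]
  structure(df, scaling = scaling, class = c("training_set", "data.frame"))
}

#' @export
print.training_set <- function(x, ...) {
  s <- attr(x, "scaling")
  cat("Training set:", nrow(x), "tuples (a, V, da/dt); scaling divisors a =",
      s[["a"]], ", V =", s[["v"]], ", da/dt =", s[["dadt"]], "\n")
  invisible(x)
}

#' Undo the training-set scaling
#' @param ts a [build_training_set()] result (for its scaling constants).
#' @param a_scaled,v_scaled,dadt_scaled scaled values.
#' @return A list with unscaled `a`, `v`, `dadt`.
#' @export
unscale_training <- function(ts, a_scaled, v_scaled, dadt_scaled) {
  s <- attr(ts, "scaling")
  list(a = a_scaled * s[["a"]], v = v_scaled * s[["v"]],
       dadt = dadt_scaled * s[["dadt"]])
}

#' Read and write training sets (CSV plus JSON sidecar)
#'
#' The CSV holds columns `a, v_mV, dadt_per_ms, a_scaled, v_scaled,
#' dadt_scaled`; the sidecar `<path>.json` records the scaling divisors and
#' sample count.
#'
#' @param ts a `training_set`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_training_set` returns the `training_set`.
#' @export
write_training_set <- function(ts, path) {
  df <- data.frame(a = ts$a, v_mV = ts$v, dadt_per_ms = ts$dadt,
                   a_scaled = ts$a_scaled, v_scaled = ts$v_scaled,
                   dadt_scaled = ts$dadt_scaled)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  s <- attr(ts, "scaling")
  jsonlite::write_json(list(package = "iongate", format = 1L,
                            scaling = as.list(s), n = nrow(ts)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scaling <- unlist(side$scaling)
  est <- data.frame(a = df$a, v = df$v_mV, dadt = df$dadt_per_ms,
                    valid = TRUE)
  build_training_set(est, scaling = scaling)
}
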