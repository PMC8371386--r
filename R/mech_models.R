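# Physical constants (CODATA), fixed package-wide.
.R_GAS   <- 8.314    # J K^-1 mol^-1
.FARADAY <- 96485    # C mol^-1

# Units throughout the package: time ms, voltage mV, current nA,
# conductance uS, concentration mM; all transition rates ms^-1.

#' Voltage-dependent transition rate constants for one gate
#'
#' A Hodgkin-Huxley gate is governed by two voltage-dependent transition
#' rates, the opening rate \eqn{\alpha(V) = A_\alpha \exp(B_\alpha V)} and the
#' closing rate \eqn{\beta(V) = A_\beta \exp(B_\beta V)}. The four constants
#' \eqn{\{A_\alpha, B_\alpha, A_\beta, B_\beta\}} fully parameterise the gate.
#'
#' @param A_alpha,A_beta rate prefactors (ms^-1); must be strictly positive.
#' @param B_alpha,B_beta voltage sensitivities (mV^-1); sign encodes the
#'   direction of voltage dependence.
#' @return An object of class `rate_params`.
#' @export
#' @examples
#' p <- rate_params(2.26e-4, 0.0699, 3.45e-5, -0.05462)
#' gate_steady_state(0, p)
rate_params <- function(A_alpha, B_alpha, A_beta, B_beta) {
  vals <- c(A_alpha = A_alpha, B_alpha = B_alpha,
            A_beta = A_beta, B_beta = B_beta)
  if (any(!is.finite(vals)))
    stop("rate parameters must be finite")
  if (A_alpha <= 0 || A_beta <= 0)
    stop("rate prefactors A_alpha and A_beta must be strictly positive")
  structure(as.list(vals), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Gate transition rates: alpha(V) = ", format(x$A_alpha),
      " * exp(", format(x$B_alpha), " V),  beta(V) = ", format(x$A_beta),
      " * exp(", format(x$B_beta), " V)  [ms^-1, V in mV]\n", sep = "")
  invisible(x)
}

#' Evaluate an exponential transition rate
#'
#' The canonical Eyring-type form \eqn{k(V) = A \exp(B V)} used for every
#' transition rate in the package.
#'
#' @param V membrane voltage (mV); vectorised.
#' @param A rate prefactor (ms^-1), strictly positive.
#' @param B voltage sensitivity (mV^-1).
#' @return Rate in ms^-1, strictly positive.
#' @export
transition_rate <- function(V, A, B) {
  if (!is.finite(A) || A <= 0) stop("rate prefactor A must be positive")
  A * exp(B * V)
}

#' Gate kinetics: right-hand side, steady state and time constant
#'
#' For open probability `x` with opening rate \eqn{\alpha(V)} and closing rate
#' \eqn{\beta(V)}, mass-action kinetics give
#' \eqn{dx/dt = \alpha(V)(1-x) - \beta(V)x}. At fixed voltage the solution
#' relaxes exponentially to \eqn{x_\infty = \alpha/(\alpha+\beta)} with time
#' constant \eqn{\tau = 1/(\alpha+\beta)}.
#'
#' `x` is deliberately not clipped to \[0, 1\]: state-space estimates may
#' transiently leave the unit interval and must be propagated as-is.
#'
#' @param x open probability (dimensionless); vectorised.
#' @param V membrane voltage (mV); vectorised.
#' @param p a [rate_params()] object.
#' @return `gate_rhs`: dx/dt in ms^-1. `gate_steady_state`: value in (0, 1).
#'   `gate_time_constant`: time constant in ms.
#' @export
gate_rhs <- function(x, V, p) {
  a <- transition_rate(V, p$A_alpha, p$B_alpha)
  b <- transition_rate(V, p$A_beta, p$B_beta)
  a * (1 - x) - b * x
}

#' @rdname gate_rhs
#' @export
gate_steady_state <- function(V, p) {
  a <- transition_rate(V, p$A_alpha, p$B_alpha)
  b <- transition_rate(V, p$A_beta, p$B_beta)
  a / (a + b)
}

#' @rdname gate_rhs
#' @export
gate_time_constant <- function(V, p) {
  a <- transition_rate(V, p$A_alpha, p$B_alpha)
  b <- transition_rate(V, p$A_beta, p$B_beta)
  1 / (a + b)
}

#' Nernst (reversal) potential for an ionic species
#'
#' \eqn{E = (RT/zF)\,\ln([K]_o/[K]_i)}, returned in mV. Defaults correspond
#' to a potassium current at room temperature with 4 mM extracellular and
#' 110 mM intracellular K+, giving about -84.1 mV.
#'
#' @param K_out extracellular concentration (mM).
#' @param K_in intracellular concentration (mM).
#' @param temperature absolute temperature (K).
#' @param valency ion valency (1 for K+).
#' @return Reversal potential in mV.
#' @export
nernst_potential <- function(K_out = 4, K_in = 110,
                             temperature = 294.55, valency = 1) {
  if (K_out <= 0 || K_in <= 0) stop("concentrations must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  1000 * .R_GAS * temperature / (valency * .FARADAY) * log(K_out / K_in)
}

#' Ohmic current through gated channels
#'
#' \eqn{I = g\,a\,r\,(V - E)}: maximal conductance times the open
#' probabilities of the independent activation (`a`) and inactivation (`r`)
#' gates times the driving force. With g in uS and voltages in mV the current
#' is in nA.
#'
#' @param a,r open probabilities; vectorised.
#' @param V membrane voltage (mV).
#' @param g maximal conductance (uS), positive.
#' @param E reversal potential (mV).
#' @return Current in nA.
#' @export
hh_current <- function(a, r, V, g, E) {
  if (g <= 0) stop("conductance g must be positive")
  g * a * r * (V - E)
}

#' Two-gate Hodgkin-Huxley channel model
#'
#' The candidate hERG/IKr model: an Ohmic current gated by a slow activation
#' gate `a` and a fast, independent inactivation gate `r`, each following
#' first-order kinetics with exponential voltage-dependent rates
#' (8 kinetic parameters plus the conductance).
#'
#' @param g maximal conductance (uS).
#' @param activation [rate_params()] for the a-gate.
#' @param inactivation [rate_params()] for the r-gate.
#' @return Object of class `hh_model`.
#' @export
hh_model <- function(g, activation, inactivation) {
  stopifnot(inherits(activation, "rate_params"),
            inherits(inactivation, "rate_params"))
  if (!is.finite(g) || g <= 0) stop("conductance g must be positive")
  structure(list(g = g, activation = activation, inactivation = inactivation),
            class = "hh_model")
}

#' @export
print.hh_model <- function(x, ...) {
  cat("Hodgkin-Huxley channel model (I = g a r (V - E)), g =",
      format(x$g), "uS\n")
  cat("  activation  : "); print(x$activation)
  cat("  inactivation: "); print(x$inactivation)
  invisible(x)
}

#' Three-state Markov activation model
#'
#' A linear activation chain C1 <-> C2 <-> O, each of the four transition
#' rates of the form \eqn{A \exp(B V)}, combined with the same independent
#' inactivation gate and Ohmic current as [hh_model()]. The open-state
#' occupancy plays the role of the activation variable; at fixed voltage it
#' relaxes as a sum of two exponentials, which a single first-order gate
#' cannot reproduce.
#'
#' @param g maximal conductance (uS).
#' @param k12,k21,k23,k32 transition rates of the chain as `c(A, B)` pairs
#'   (ms^-1, mV^-1): `k12` C1->C2, `k21` C2->C1, `k23` C2->O, `k32` O->C2.
#' @param inactivation [rate_params()] for the shared r-gate.
#' @return Object of class `three_state_model`.
#' @export
three_state_model <- function(g, k12, k21, k23, k32, inactivation) {
  stopifnot(inherits(inactivation, "rate_params"))
  if (!is.finite(g) || g <= 0) stop("conductance g must be positive")
  rates <- list(k12 = k12, k21 = k21, k23 = k23, k32 = k32)
  for (nm in names(rates)) {
    k <- rates[[nm]]
    if (length(k) != 2 || any(!is.finite(k)))
      stop("rate ", nm, " must be a finite c(A, B) pair")
    if (k[[1]] <= 0) stop("rate prefactor of ", nm, " must be positive")
  }
  structure(c(rates, list(g = g, inactivation = inactivation)),
            class = "three_state_model")
}

#' @export
print.three_state_model <- function(x, ...) {
  cat("Three-state Markov activation model (C1 <-> C2 <-> O), g =",
      format(x$g), "uS\n")
  for (nm in c("k12", "k21", "k23", "k32"))
    cat(sprintf("  %s: %g * exp(%g V) ms^-1\n", nm, x[[nm]][1], x[[nm]][2]))
  cat("  inactivation: "); print(x$inactivation)
  invisible(x)
}

#' Rate matrix, derivatives and steady state of the three-state chain
#'
#' `three_state_rate_matrix` returns the 3x3 generator Q such that
#' \eqn{ds/dt = Q s} for the occupancy vector \eqn{s = (C1, C2, O)}.
#' Columns of Q sum to zero, so occupancy is conserved exactly.
#'
#' @param V membrane voltage (mV), scalar.
#' @param p a [three_state_model()].
#' @return `three_state_rate_matrix`: a 3x3 matrix. `three_state_rhs`: the
#'   derivative triple (ms^-1), summing to zero. `three_state_steady_state`:
#'   the stationary occupancy triple, summing to one.
#' @export
three_state_rate_matrix <- function(V, p) {
  k12 <- transition_rate(V, p$k12[1], p$k12[2])
  k21 <- transition_rate(V, p$k21[1], p$k21[2])
  k23 <- transition_rate(V, p$k23[1], p$k23[2])
  k32 <- transition_rate(V, p$k32[1], p$k32[2])
  matrix(c(-k12,  k21,        0,
            k12, -(k21 + k23), k32,
              0,  k23,       -k32),
         nrow = 3, byrow = TRUE)
}

#' @rdname three_state_rate_matrix
#' @param s occupancy triple (C1, C2, O).
#' @export
three_state_rhs <- function(s, V, p) {
  if (any(!is.finite(s))) stop("occupancies must be finite")
  as.vector(three_state_rate_matrix(V, p) %*% s)
}

#' @rdname three_state_rate_matrix
#' @export
three_state_steady_state <- function(V, p) {
  Q <- three_state_rate_matrix(V, p)
  if (all(abs(Q) < .Machine$double.xmin))
    stop("degenerate rate matrix: all rates are zero")
  # stationary distribution: null vector of Q, normalised; replace one
  # (redundant) balance equation by the conservation constraint
  A <- rbind(Q[1:2, ], rep(1, 3))
  s <- solve(A, c(0, 0, 1))
  as.vector(s)
}

#' Literature-plausible default parameter sets
#'
#' `candidate_hh_params()` returns the default two-gate Hodgkin-Huxley hERG
#' model with kinetic constants in the range reported for room-temperature
#' hERG recordings (slow activation, time constants of order seconds near
#' 0 mV; fast inactivation, tens of ms), with conductance 1 uS as used in the
#' synthetic studies. `ground_truth_params()` returns the default three-state
#' activation model used as the data-generating ("ground truth") process: its
#' C1<->C2 step matches the candidate's slow activation rates while the
#' C2<->O step is roughly an order of magnitude faster, so deactivation at
#' tail voltages shows two well-separated time constants. Both are defaults,
#' intended to be replaced by values loaded with [read_params_json()] when an
#' externally identified parameter set is available.
#'
#' @param g maximal conductance (uS); the synthetic studies use 1 uS.
#' @return An [hh_model()] or [three_state_model()].
#' @export
candidate_hh_params <- function(g = 1) {
  hh_model(
    g = g,
    activation   = rate_params(2.26e-4, 0.0699,  3.45e-5, -0.05462),
    inactivation = rate_params(5.15e-3, -0.03158, 0.0873,  8.91e-3)
  )
}

#' @rdname candidate_hh_params
#' @export
ground_truth_params <- function(g = 1) {
  three_state_model(
    g = g,
    k12 = c(2.26e-4, 0.0699),
    k21 = c(3.45e-5, -0.05462),
    k23 = c(6.0e-3, 0.03),
    k32 = c(1.5e-3, -0.035),
    inactivation = rate_params(5.15e-3, -0.03158, 0.0873, 8.91e-3)
  )
}

#' Read and write model parameter files
#'
#' Parameters are stored as a flat JSON object whose key names carry explicit
#' unit suffixes, e.g. `g_uS`, `act_A_alpha_per_ms`, `act_B_alpha_per_mV`.
#' Three-state chain rates use keys `k12_A_per_ms`/`k12_B_per_mV` etc. A
#' `model` key (`"hh"` or `"three_state"`) selects the class.
#'
#' @param model an [hh_model()] or [three_state_model()].
#' @param path file path.
#' @return `read_params_json` returns the reconstructed model object.
#' @export
write_params_json <- function(model, path) {
  rp_to_kv <- function(prefix, p)
    stats::setNames(list(p$A_alpha, p$B_alpha, p$A_beta, p$B_beta),
                    paste0(prefix, c("_A_alpha_per_ms", "_B_alpha_per_mV",
                                     "_A_beta_per_ms", "_B_beta_per_mV")))
  if (inherits(model, "hh_model")) {
    kv <- c(list(model = "hh", g_uS = model$g),
            rp_to_kv("act", model$activation),
            rp_to_kv("inact", model$inactivation))
  } else if (inherits(model, "three_state_model")) {
    kv <- list(model = "three_state", g_uS = model$g)
    for (nm in c("k12", "k21", "k23", "k32")) {
      kv[[paste0(nm, "_A_per_ms")]] <- model[[nm]][1]
      kv[[paste0(nm, "_B_per_mV")]] <- model[[nm]][2]
    }
    kv <- c(kv, rp_to_kv("inact", model$inactivation))
  } else stop("unsupported model class")
  jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  rp_from_kv <- function(prefix)
    rate_params(kv[[paste0(prefix, "_A_alpha_per_ms")]],
                kv[[paste0(prefix, "_B_alpha_per_mV")]],
                kv[[paste0(prefix, "_A_beta_per_ms")]],
                kv[[paste0(prefix, "_B_beta_per_mV")]])
  if (identical(kv$model, "hh")) {
    hh_model(kv$g_uS, rp_from_kv("act"), rp_from_kv("inact"))
  } else if (identical(kv$model, "three_state")) {
    three_state_model(
      kv$g_uS,
      k12 = c(kv$k12_A_per_ms, kv$k12_B_per_mV),
      k21 = c(kv$k21_A_per_ms, kv$k21_B_per_mV),
      k23 = c(kv$k23_A_per_ms, kv$k23_B_per_mV),
      k32 = c(kv$k32_A_per_ms, kv$k32_B_per_mV),
      inactivation = rp_from_kv("inact"))
  } else stop("unknown model type in parameter file: ", kv$model)
}
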