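# Least-squares fitting of the candidate Hodgkin-Huxley model: the baseline
# every neural gate model is compared against.

.theta_names <- c("act_A_alpha", "act_B_alpha", "act_A_beta", "act_B_beta",
                  "inact_A_alpha", "inact_B_alpha", "inact_A_beta",
                  "inact_B_beta", "g")

.model_to_theta <- function(model) {
  a <- model$activation; r <- model$inactivation
  c(log(a$A_alpha), a$B_alpha, log(a$A_beta), a$B_beta,
    log(r$A_alpha), r$B_alpha, log(r$A_beta), r$B_beta, log(model$g))
}

.theta_to_model <- function(theta) {
  hh_model(g = exp(theta[9]),
           activation = rate_params(exp(theta[1]), theta[2],
                                    exp(theta[3]), theta[4]),
           inactivation = rate_params(exp(theta[5]), theta[6],
                                      exp(theta[7]), theta[8]))
}

#' Fit the candidate Hodgkin-Huxley model to current traces
#'
#' Minimises the sum of squared residuals between simulated and measured
#' currents over the 8 kinetic parameters and (optionally) the conductance.
#' Rate prefactors and the conductance are optimised on the log scale,
#' voltage sensitivities untransformed, with box bounds
#' A in \[1e-7, 1e3\] ms^-1 and B in \[-1, 1\] mV^-1 plus a soft penalty on
#' rates exceeding 1000 ms^-1 at +/-120 mV (standard practice to keep the
#' model numerically sane at extreme voltages). Seeded multi-start L-BFGS-B;
#' the best start is returned. Step-protocol traces are simulated with the
#' exact piecewise-exponential propagator, so objective evaluations are
#' cheap; `fit_sample_ms` optionally thins the residual grid.
#'
#' @param traces a [current_trace()] or list of them, each with its protocol
#'   attached (or supply `protocols`).
#' @param protocols optional list of protocols matching `traces`.
#' @param init initial [hh_model()] guess; defaults to
#'   [candidate_hh_params()].
#' @param E reversal potential (mV).
#' @param cfg a [sim_config()].
#' @param seed integer seed for the multi-start perturbations.
#' @param n_starts number of optimisation starts (first = `init`).
#' @param blank_ms capacitance blanking applied to the residuals (0 for
#'   synthetic data).
#' @param fit_g fit the conductance (TRUE) or keep it at `init$g`.
#' @param fit_sample_ms thin the data to roughly this sampling interval for
#'   the objective (ms); `NULL` uses every sample.
#' @param maxit maximum L-BFGS-B iterations per start.
#' @return Object of class `fit_result`: list with the fitted `model`, the
#'   best `objective`, per-start diagnostics `starts`, and the `seed`.
#' @export
fit_candidate_model <- function(traces, protocols = NULL,
                                init = candidate_hh_params(),
                                E = nernst_potential(), cfg = sim_config(),
                                seed = 1, n_starts = 3, blank_ms = 0,
                                fit_g = TRUE, fit_sample_ms = 5,
                                maxit = 200) {
  if (inherits(traces, "current_trace")) traces <- list(traces)
  if (is.null(protocols))
    protocols <- lapply(traces, function(tr) tr$protocol)
  if (any(vapply(protocols, is.null, logical(1))))
    stop("each trace needs a protocol")
  stopifnot(length(traces) >= 1, length(traces) == length(protocols))

  # pre-extract thinned, masked data per trace; the objective simulates on
  # the thinned grid directly, which cuts its cost by the thinning factor
  data <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]; p <- protocols[[i]]
    dt <- stats::median(diff(tr$times))
    k <- if (is.null(fit_sample_ms)) 1L
         else max(1L, round(fit_sample_ms / dt))
    thin <- seq(1L, length(tr$times), by = k)
    keep <- capacitance_mask(tr$times[thin], p, blank_ms)
    cfg_i <- cfg
    cfg_i$sample_ms <- k * dt
    list(I = tr$current[thin][keep], protocol = p, cfg = cfg_i,
         keep = keep, n_thin = length(thin))
  })

  free <- if (fit_g) 1:9 else 1:8
  lower <- c(rep(c(log(1e-7), -1), 4), log(1e-3))[free]
  upper <- c(rep(c(log(1e3), 1), 4), log(1e3))[free]
  # voltage sensitivities live on a ~20x smaller scale than log-rates;
  # without parscale the finite-difference gradients are too coarse for
  # the curved g-vs-rate valleys of this objective
  parscale <- c(rep(c(1, 0.05), 4), 1)[free]
  theta_full <- .model_to_theta(init)

  objective <- function(theta) {
    tf <- theta_full
    tf[free] <- theta
    model <- .theta_to_model(tf)
    ssr <- 0
    for (d in data) {
      sim <- simulate_current(model, d$protocol, d$cfg, E, method = "auto")
      ssr <- ssr + sum((sim$current[seq_len(d$n_thin)][d$keep] - d$I)^2)
    }
    # soft cap on rates at extreme voltages
    pen <- 0
    for (p in list(model$activation, model$inactivation)) {
      for (k in list(c(p$A_alpha, p$B_alpha), c(p$A_beta, p$B_beta))) {
        kmax <- max(transition_rate(-120, k[1], k[2]),
                    transition_rate(120, k[1], k[2]))
        if (kmax > 1e3) pen <- pen + 1e6 * log(kmax / 1e3)^2
      }
    }
    ssr + pen
  }

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    th0 <- theta_full[free]
    if (s > 1) {
      jitter <- stats::rnorm(length(free), 0,
                             rep_len(c(0.5, 0.02), length(free)))
      th0 <- pmin(pmax(th0 + jitter, lower), upper)
    }
    fit <- tryCatch(
      stats::optim(th0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e1,
                                  parscale = parscale)),
      error = function(e) NULL)
    starts[[s]] <- fit
  }
  ok <- !vapply(starts, is.null, logical(1))
  if (!any(ok))
    stop("candidate-model fit failed: no optimisation start converged")
  objs <- vapply(starts, function(f) if (is.null(f)) Inf else f$value,
                 numeric(1))
  best <- starts[[which.min(objs)]]
  tf <- theta_full
  tf[free] <- best$par
  structure(list(model = .theta_to_model(tf), objective = best$value,
                 starts = data.frame(start = seq_len(n_starts),
                                     objective = objs,
                                     convergence = vapply(starts, function(f)
                                       if (is.null(f)) NA_integer_
                                       else f$convergence, integer(1))),
                 seed = seed, counts = best$counts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Candidate-model fit: objective =", format(x$objective, digits = 6),
      "over", nrow(x$starts), "start(s)\n")
  print(x$model)
  invisible(x)
}
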