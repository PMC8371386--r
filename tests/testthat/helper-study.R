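# Synthetic-data studies are expensive (candidate fit + two network
# trainings each), so they are computed lazily once per test session and
# shared between the test files that interrogate them. The master seed is
# fixed at 42; every stage seed derives from it inside the study driver.
#
# Scaling note: the studies here use the compact 3x32 network, 450 Adam
# epochs and 16000 training tuples rather than the reference 5x200
# architecture, purely to keep the suite inside a CPU-only test budget; the
# architecture is configuration, not substance.

.study_cache <- new.env(parent = emptyenv())

study_seed <- 42

get_study <- function(which = c("ground", "control", "pr34")) {
  which <- match.arg(which)
  if (!is.null(.study_cache[[which]])) return(.study_cache[[which]])
  cfg <- switch(which,
    ground = study_config(generator = "ground_truth", seed = study_seed),
    control = study_config(generator = "candidate", seed = study_seed),
    pr34 = study_config(
      generator = "ground_truth", seed = study_seed,
      train_protocols = list(pr3 = pr3_like(), pr4 = pr4_like()),
      predict_protocols = list(pr5 = pr5_like())))
  res <- run_synthetic_study(cfg)
  assign(which, res, envir = .study_cache)
  res
}

# relative residual of the best k-exponential-plus-constant fit to a tail
# trace: decay rates from a log grid (all pairs for k = 2), amplitudes
# solved linearly
tail_exp_residual <- function(times, values, k) {
  rss_for <- function(lam) {
    X <- cbind(1, vapply(lam, function(l) exp(-l * times),
                         numeric(length(times))))
    sum(stats::lm.fit(X, values)$residuals^2)
  }
  rates <- exp(seq(log(1e-4), log(0.5), length.out = 60))
  sets <- if (k == 1) lapply(rates, identity) else
    unlist(lapply(seq_along(rates)[-length(rates)], function(i)
      lapply(seq(i + 1, length(rates)), function(j) rates[c(i, j)])),
      recursive = FALSE)
  rss <- vapply(sets, rss_for, numeric(1))
  lam0 <- sets[[which.min(rss)]]
  # refine the grid optimum locally on the log-rate scale
  opt <- stats::optim(log(lam0), function(ll) rss_for(exp(ll)),
                      method = if (k == 1) "Brent" else "Nelder-Mead",
                      lower = if (k == 1) log(lam0) - 1 else -Inf,
                      upper = if (k == 1) log(lam0) + 1 else Inf)
  sqrt(min(min(rss), opt$value) / sum((values - mean(values))^2))
}
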