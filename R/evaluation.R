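# Quantitative model comparison: mean-absolute-error tables and the
# state-space coverage / extrapolation diagnostics that explain when a
# trained neural gate is interpolating and when it is (unreliably)
# extrapolating.

#' Mean absolute error between two aligned current traces
#'
#' @param pred,data [current_trace()]s on identical time stamps.
#' @param mask optional logical vector of samples to include (e.g. a
#'   [capacitance_mask()]); `NULL` uses all samples.
#' @return MAE in nA.
#' @export
mean_absolute_error <- function(pred, data, mask = NULL) {
  stopifnot(inherits(pred, "current_trace"), inherits(data, "current_trace"))
  if (length(pred$times) != length(data$times) ||
      max(abs(pred$times - data$times)) > 1e-6)
    stop("traces are misaligned: time stamps differ")
  d <- abs(pred$current - data$current)
  if (!is.null(mask)) d <- d[mask]
  mean(d)
}

#' State-space trajectory of an activation model under a protocol
#'
#' Simulates the model and pairs the activation variable with the voltage at
#' every sample, giving the (a, V) path the protocol drives the gate
#' through. Samples at step discontinuities are flagged, since they are the
#' jump endpoints in state-space plots.
#'
#' @param model a simulable model object.
#' @param protocol a protocol object.
#' @param cfg a [sim_config()].
#' @return Data frame with columns `time`, `a`, `v`, `boundary`.
#' @export
state_space_trajectory <- function(model, protocol, cfg = sim_config()) {
  tr <- simulate_states(model, protocol, cfg)
  a <- if ("o" %in% colnames(tr$states)) tr$states[, "o"] else tr$states[, "a"]
  V <- voltage_at(protocol, tr$times)
  boundary <- if (inherits(protocol, "step_protocol"))
    tr$times %in% step_boundaries(protocol) else rep(FALSE, length(tr$times))
  data.frame(time = tr$times, a = a, v = V, boundary = boundary)
}

#' Occupancy histogram of (a, V) state space
#'
#' Bins trajectory samples on a fixed 2-D grid. The default grid covers
#' a in \[0, 1\] and V in \[-140, 60\] mV with 50 bins per axis; samples
#' outside the grid are clamped into the edge bins so every sample is
#' counted.
#'
#' @param trajectories a data frame from [state_space_trajectory()] or a
#'   list of them.
#' @param a_breaks,v_breaks bin edges.
#' @return Object of class `coverage_map`: counts matrix (rows = a bins,
#'   columns = V bins) plus the bin edges.
#' @export
coverage_map <- function(trajectories,
                         a_breaks = seq(0, 1, length.out = 51),
                         v_breaks = seq(-140, 60, length.out = 51)) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  if (!length(trajectories)) stop("no trajectories supplied")
  df <- do.call(rbind, lapply(trajectories, function(x) x[, c("a", "v")]))
  na <- length(a_breaks) - 1L
  nv <- length(v_breaks) - 1L
  ia <- pmin(pmax(findInterval(df$a, a_breaks, rightmost.closed = TRUE),
                  1L), na)
  iv <- pmin(pmax(findInterval(df$v, v_breaks, rightmost.closed = TRUE),
                  1L), nv)
  counts <- matrix(0L, na, nv)
  tab <- table(factor(ia, levels = seq_len(na)),
               factor(iv, levels = seq_len(nv)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, a_breaks = a_breaks, v_breaks = v_breaks),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat("Coverage map:", nrow(x$counts), "x", ncol(x$counts), "bins,",
      sum(x$counts), "samples,", sum(x$counts > 0), "occupied bins\n")
  invisible(x)
}

#' Fraction of a trajectory outside the trained state-space region
#'
#' For each prediction sample, checks whether any training sample fell
#' within `radius` bins (Chebyshev neighbourhood) of its (a, V) bin;
#' samples outside the grid entirely count as unexplored. A large fraction
#' means the neural gate is being asked to extrapolate, which is exactly
#' when its predictions stop being trustworthy.
#'
#' @param trajectory data frame from [state_space_trajectory()] (or any
#'   frame with `a` and `v` columns).
#' @param cmap a [coverage_map()] of the training trajectories.
#' @param radius neighbourhood radius in bins.
#' @param warn_threshold emit a warning if the fraction exceeds this value;
#'   `NULL` disables the warning.
#' @return Fraction in \[0, 1\].
#' @export
extrapolation_fraction <- function(trajectory, cmap, radius = 1,
                                   warn_threshold = NULL) {
  stopifnot(inherits(cmap, "coverage_map"))
  na <- nrow(cmap$counts); nv <- ncol(cmap$counts)
  ia <- findInterval(trajectory$a, cmap$a_breaks, rightmost.closed = TRUE)
  iv <- findInterval(trajectory$v, cmap$v_breaks, rightmost.closed = TRUE)
  outside <- ia < 1 | ia > na | iv < 1 | iv > nv
  occ <- cmap$counts > 0
  covered <- logical(length(ia))
  for (k in which(!outside)) {
    ra <- max(1, ia[k] - radius):min(na, ia[k] + radius)
    rv <- max(1, iv[k] - radius):min(nv, iv[k] + radius)
    covered[k] <- any(occ[ra, rv])
  }
  frac <- mean(!covered)
  if (!is.null(warn_threshold) && frac > warn_threshold)
    warning(sprintf(paste0("%.1f%% of the trajectory lies outside the ",
                           "trained state-space region"), 100 * frac))
  frac
}

#' Write a coverage map as CSV
#'
#' Long format with columns `a_lo, a_hi, v_lo, v_hi, count`.
#' @param cmap a [coverage_map()].
#' @param path file path.
#' @export
write_coverage_csv <- function(cmap, path) {
  na <- nrow(cmap$counts); nv <- ncol(cmap$counts)
  df <- data.frame(
    a_lo = rep(cmap$a_breaks[-(na + 1)], nv),
    a_hi = rep(cmap$a_breaks[-1], nv),
    v_lo = rep(cmap$v_breaks[-(nv + 1)], each = na),
    v_hi = rep(cmap$v_breaks[-1], each = na),
    count = as.vector(cmap$counts))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
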