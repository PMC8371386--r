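# End-to-end synthetic-data study: generate data from a known model, fit
# the candidate Hodgkin-Huxley model, train the neural gate models by
# state-space derivative regression, and compare predictions on unseen
# protocols. Deterministic given the master seed; all per-stage seeds are
# derived from it by a fixed counter scheme (seed + 1, 2, ... per protocol
# for noise; +101 for the fit; +201 for subsampling; +301/+401 for the two
# trainings).

#' Generate a synthetic voltage-clamp dataset
#'
#' Simulates the generating model over each protocol from its steady state
#' at the holding voltage and adds i.i.d. Gaussian observation noise
#' (default SD 0.1 nA) with a per-protocol seed derived from the master
#' seed. Both the clean truth and the noisy observation are returned.
#' `make_ground_truth_dataset` uses the three-state ("ground truth") model,
#' so the dataset carries genuine model discrepancy relative to the
#' candidate; `make_no_discrepancy_dataset` generates from the candidate
#' model itself, the no-discrepancy control.
#'
#' @param params generating model ([three_state_model()] or [hh_model()]);
#'   conductance defaults to 1 uS in both default parameter sets.
#' @param protocols named list of protocol objects.
#' @param noise_sd observation noise SD (nA).
#' @param seed master integer seed.
#' @param cfg a [sim_config()].
#' @param E reversal potential (mV).
#' @return Object of class `synthetic_dataset`: per protocol a list with
#'   `clean` and `noisy` [current_trace()]s; attributes record the
#'   generator, seed and noise SD.
#' @export
make_ground_truth_dataset <- function(params = ground_truth_params(),
                                      protocols = list(pr3 = pr3_like(),
                                                       pr5 = pr5_like()),
                                      noise_sd = 0.1, seed = 1,
                                      cfg = sim_config(),
                                      E = nernst_potential()) {
  stopifnot(inherits(params, "three_state_model"))
  .make_dataset(params, protocols, noise_sd, seed, cfg, E)
}

#' @rdname make_ground_truth_dataset
#' @export
make_no_discrepancy_dataset <- function(params = candidate_hh_params(),
                                        protocols = list(pr3 = pr3_like(),
                                                         pr5 = pr5_like()),
                                        noise_sd = 0.1, seed = 1,
                                        cfg = sim_config(),
                                        E = nernst_potential()) {
  stopifnot(inherits(params, "hh_model"))
  .make_dataset(params, protocols, noise_sd, seed, cfg, E)
}

.make_dataset <- function(params, protocols, noise_sd, seed, cfg, E) {
  if (is.null(names(protocols)) || any(!nzchar(names(protocols))))
    stop("protocols must be a named list")
  out <- vector("list", length(protocols))
  names(out) <- names(protocols)
  for (i in seq_along(protocols)) {
    clean <- simulate_current(params, protocols[[i]], cfg, E)
    noisy <- add_noise(clean, noise_sd, seed = seed + i)
    out[[i]] <- list(clean = clean, noisy = noisy)
  }
  structure(out, params = params, seed = seed, noise_sd = noise_sd,
            E = E, class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x), "protocol(s) [",
      paste(names(x), collapse = ", "), "], noise SD",
      attr(x, "noise_sd"), "nA, seed", attr(x, "seed"), "\n")
  invisible(x)
}

#' Configuration of a synthetic-data study
#'
#' Collects every knob of [run_synthetic_study()] in one validated object.
#' The defaults reproduce the study design: train on activation + deactivation
#' step protocols, predict the unseen inactivation-protocol surrogate,
#' Gaussian noise of 0.1 nA, conductance 1 uS, steady state at -80 mV.
#'
#' @param generator `"ground_truth"` (three-state data, model discrepancy
#'   present) or `"candidate"` (no-discrepancy control).
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param train_protocols,predict_protocols named lists of protocols.
#' @param noise_sd observation noise SD (nA).
#' @param cfg a [sim_config()].
#' @param spec [network_spec()] used for both neural gates.
#' @param epochs,lr,batch_size training settings (see [train_network()]).
#' @param subsample number of training tuples drawn (without replacement)
#'   from the assembled training set; `Inf` keeps all.
#' @param blank_ms blanking window applied before spline fitting and in the
#'   fit residuals.
#' @param smoothing spline smoothing (see [fit_segment_splines()]).
#' @param fit_n_starts multi-start count for the candidate fit.
#' @param out_dir optional directory: study artefacts (MAE table,
#'   checkpoints, coverage map, config) are written into a
#'   config-hash-named subdirectory.
#' @return Object of class `study_config`.
#' @export
study_config <- function(generator = c("ground_truth", "candidate"),
                         seed = 1,
                         train_protocols = list(pr3 = pr3_like(),
                                                pr5 = pr5_like()),
                         predict_protocols = list(pr4 = pr4_like()),
                         noise_sd = 0.1, cfg = sim_config(),
                         spec = network_spec(hidden = rep(32, 3)),
                         epochs = 450, lr = 3e-3, batch_size = Inf,
                         subsample = 16000, blank_ms = 5, smoothing = NULL,
                         fit_n_starts = 2, out_dir = NULL) {
  generator <- match.arg(generator)
  stopifnot(length(train_protocols) >= 1, length(predict_protocols) >= 1)
  structure(list(generator = generator, seed = as.integer(seed),
                 train_protocols = train_protocols,
                 predict_protocols = predict_protocols,
                 noise_sd = noise_sd, cfg = cfg, spec = spec,
                 epochs = epochs, lr = lr, batch_size = batch_size,
                 subsample = subsample, blank_ms = blank_ms,
                 smoothing = smoothing, fit_n_starts = fit_n_starts,
                 out_dir = out_dir),
            class = "study_config")
}

# draw a seeded subsample of a training set, preserving class and scaling
.subsample_training_set <- function(ts, n, seed) {
  if (!is.finite(n) || n >= nrow(ts)) return(ts)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sort(sample.int(nrow(ts), n))
  out <- ts[idx, ]
  attr(out, "scaling") <- attr(ts, "scaling")
  class(out) <- class(ts)
  out
}

#' Run the synthetic-data study end to end
#'
#' Stages: (1) generate noisy training and prediction data from the
#' configured generator; (2) fit the candidate Hodgkin-Huxley model to the
#' noisy training traces; (3) run state-space estimation on the training
#' traces (using the trusted inactivation gate and the known conductance)
#' and assemble the scaled training set; (4) train the full-replacement and
#' discrepancy neural gates (the discrepancy gate corrects the *fitted*
#' candidate activation); (5) simulate every model over every protocol and
#' tabulate mean absolute errors against the noisy data (all samples, the
#' synthetic-data convention); (6) build the training-coverage map from the
#' fitted candidate's state-space trajectories and compute the
#' extrapolation fraction of each prediction protocol. Any stage failure
#' aborts with the stage name. The result is fully determined by the
#' configuration.
#'
#' @param config a [study_config()].
#' @return Object of class `study_report`: list with the dataset, fitted
#'   candidate (`fit`), trained models (`nn_f`, `nn_d`), the `mae` table
#'   (rows original/NN-f/NN-d), `coverage`, `extrapolation` fractions, and
#'   the training set size.
#' @export
run_synthetic_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  cfg <- config$cfg
  E <- nernst_potential()
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("study stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  generator <- if (config$generator == "ground_truth")
    ground_truth_params() else candidate_hh_params()
  protos <- c(config$train_protocols, config$predict_protocols)
  dataset <- stage("generate", .make_dataset(generator, protos,
                                             config$noise_sd, seed, cfg, E))
  train_names <- names(config$train_protocols)
  pred_names <- names(config$predict_protocols)

  fit <- stage("fit_candidate", fit_candidate_model(
    lapply(dataset[train_names], `[[`, "noisy"),
    protocols = config$train_protocols,
    init = candidate_hh_params(), E = E, cfg = cfg,
    seed = seed + 101, n_starts = config$fit_n_starts,
    blank_ms = config$blank_ms))

  # trusted inactivation gate and known conductance of the generator
  r_true <- generator$inactivation
  g_true <- generator$g
  ests <- stage("state_space", lapply(train_names, function(nm)
    estimate_state_space(dataset[[nm]]$noisy, protos[[nm]], g = g_true,
                         E = E, r_params = r_true,
                         smoothing = config$smoothing,
                         blank_ms = config$blank_ms)))
  ts_full <- stage("training_set", build_training_set(ests))
  ts <- .subsample_training_set(ts_full, config$subsample, seed + 201)

  nn_f <- stage("train_nn_f", train_network(
    ts, "full", spec = config$spec, seed = seed + 301,
    epochs = config$epochs, lr = config$lr,
    batch_size = config$batch_size, inactivation = r_true, g = g_true))
  nn_d <- stage("train_nn_d", train_network(
    ts, "discrepancy", spec = config$spec,
    candidate = fit$model$activation, seed = seed + 401,
    epochs = config$epochs, lr = config$lr,
    batch_size = config$batch_size, inactivation = r_true, g = g_true))

  models <- list(original = fit$model, nn_f = nn_f, nn_d = nn_d)
  mae <- stage("evaluate", {
    tab <- vapply(names(protos), function(nm) {
      vapply(models, function(mod) {
        sim <- suppressWarnings(
          simulate_current(mod, protos[[nm]], cfg, E))
        mean_absolute_error(sim, dataset[[nm]]$noisy)
      }, numeric(1))
    }, numeric(length(models)))   # models x protocols
    data.frame(model = names(models), tab, row.names = NULL,
               check.names = FALSE)
  })

  coverage <- stage("coverage", coverage_map(
    lapply(train_names, function(nm)
      state_space_trajectory(fit$model, protos[[nm]], cfg))))
  extrap <- stage("extrapolation", vapply(pred_names, function(nm)
    extrapolation_fraction(
      state_space_trajectory(fit$model, protos[[nm]], cfg), coverage),
    numeric(1)))

  report <- structure(list(config = config, dataset = dataset, fit = fit,
                           nn_f = nn_f, nn_d = nn_d, mae = mae,
                           coverage = coverage, extrapolation = extrap,
                           n_training = nrow(ts)),
                      class = "study_report")
  if (!is.null(config$out_dir)) .write_study(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic-data study (generator:", x$config$generator,
      ", seed", x$config$seed, ")\n")
  cat("Training tuples:", x$n_training, "\n")
  cat("Mean absolute error vs noisy data (nA):\n")
  print(x$mae, row.names = FALSE, digits = 3)
  cat("Extrapolation fraction of prediction protocols:",
      paste(sprintf("%s = %.3f", names(x$extrapolation), x$extrapolation),
            collapse = ", "), "\n")
  invisible(x)
}

# write study artefacts into a config-hash-named directory (timestamp-free,
# so identical configurations map to identical paths)
.write_study <- function(report, out_dir) {
  cfgj <- jsonlite::toJSON(list(
    generator = report$config$generator, seed = report$config$seed,
    noise_sd = report$config$noise_sd,
    protocols = names(c(report$config$train_protocols,
                        report$config$predict_protocols)),
    spec = unclass(report$config$spec), epochs = report$config$epochs,
    lr = report$config$lr, subsample = report$config$subsample),
    auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfgj, tmp)
  hash <- substr(unname(tools::md5sum(tmp)), 1, 12)
  unlink(tmp)
  dir <- file.path(out_dir, paste0("study-", hash))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(cfgj, file.path(dir, "config.json"))
  utils::write.csv(report$mae, file.path(dir, "mae.csv"), row.names = FALSE)
  save_model(report$nn_f, file.path(dir, "nn_f.json"))
  save_model(report$nn_d, file.path(dir, "nn_d.json"))
  write_params_json(report$fit$model, file.path(dir, "fitted_candidate.json"))
  write_coverage_csv(report$coverage, file.path(dir, "coverage.csv"))
  jsonlite::write_json(as.list(report$extrapolation),
                       file.path(dir, "extrapolation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
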