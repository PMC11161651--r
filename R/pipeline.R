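#' End-to-end run configuration
#'
#' Bundles every stage's parameters into one object so that a complete
#' run — generate, preprocess, design, train, ensemble, explain, validate,
#' aggregate — is reproducible from the configuration and master seed
#' alone.
#'
#' @param n_per_class Synthetic records per class.
#' @param generator An [ecg_generator_config()].
#' @param preprocess A [preprocess_config()].
#' @param r_short,r_long Receptive-field targets (samples) of the two
#'   branches.
#' @param n_layers Convolutional layers per branch.
#' @param test_fraction Held-out test fraction.
#' @param n_folds Cross-validation folds.
#' @param batch_size,learning_rate,f_last,epochs,patience Training
#'   settings applied to both branches.
#' @param weight_grid Candidate long-term ensemble weights.
#' @param methods Attribution methods to run (subset of [xai_methods()]).
#' @param perturbation_step Fraction-grid step for pixel-flipping.
#' @param n_validate Records used for the pixel-flipping comparison.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL`: nothing written to disk).
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_per_class = 40,
                       generator = ecg_generator_config(),
                       preprocess = preprocess_config(),
                       r_short = 300, r_long = 5000, n_layers = 9,
                       test_fraction = 0.1, n_folds = 5,
                       batch_size = 16, learning_rate = 1e-3, f_last = 8,
                       epochs = 30, patience = 5,
                       weight_grid = seq(0.25, 3, by = 0.0025),
                       methods = c("dtd", "itg"),
                       perturbation_step = 0.05, n_validate = 20,
                       seed = 42, out_dir = NULL) {
  stopifnot(all(methods %in% xai_methods()))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Executes every stage on synthetic data and returns the artifacts plus a
#' manifest (seeds, configuration fingerprint, metrics) that makes the run
#' reproducible. With `out_dir` set, curves, metrics and summaries are
#' written as CSV/JSON files.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return List with `specs`, `fits`, `ensemble`, `test_metrics`,
#'   `auc_table`, `beat_summaries`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("generate: %d records/class", config$n_per_class)
  records <- stage("generate",
    generate_dataset(config$generator, config$n_per_class, config$seed))
  say("preprocess")
  records <- stage("preprocess", preprocess_dataset(records, config$preprocess))
  split <- stage("split",
    train_test_split_records(records, config$test_fraction, config$n_folds,
                             config$seed + 1))
  train <- do.call(c, split$folds[-1])
  val <- split$folds[[1]]

  say("design: receptive fields %d / %d", config$r_short, config$r_long)
  specs <- stage("design", list(
    short = solve_configuration(solver_constraints(config$r_short,
                                                   config$n_layers),
                                f_last = config$f_last),
    long = solve_configuration(solver_constraints(config$r_long,
                                                  config$n_layers),
                               f_last = config$f_last)))

  say("train: short-term model")
  fits <- list()
  fits$short <- stage("train", train_model(
    specs$short, train, val, batch_size = config$batch_size,
    learning_rate = config$learning_rate, f_last = config$f_last,
    epochs = config$epochs, patience = config$patience,
    seed = config$seed + 2))
  say("train: long-term model")
  fits$long <- stage("train", train_model(
    specs$long, train, val, batch_size = config$batch_size,
    learning_rate = config$learning_rate, f_last = config$f_last,
    epochs = config$epochs, patience = config$patience,
    seed = config$seed + 3))

  say("ensemble: optimizing long-term weight")
  weights <- stage("ensemble", optimize_ensemble_weight(
    list(list(short = fits$short$model, long = fits$long$model)), list(val),
    config$weight_grid))
  ens <- ecg_ensemble(fits$short$model, fits$long$model, weights)
  test_metrics <- list(short = evaluate(fits$short$model, split$test),
                       long = evaluate(fits$long$model, split$test),
                       ensemble = evaluate(ens, split$test))

  say("validate-xai: %s", paste(config$methods, collapse = ", "))
  v_records <- split$test[seq_len(min(config$n_validate, length(split$test)))]
  auc_table <- stage("validate-xai", compare_methods(
    list(short = fits$short$model, long = fits$long$model), v_records,
    methods = config$methods, step = config$perturbation_step,
    seed = config$seed, background = train[seq_len(min(50, length(train)))]))

  say("aggregate: template beats (%s)", config$methods[1])
  beat_summaries <- stage("aggregate", {
    sums <- lapply(v_records, function(r)
      record_beat_summary(r, explain(fits$long$model, r, config$methods[1],
                                     background = train[seq_len(min(50, length(train)))])))
    lapply(stats::setNames(ECG_CLASSES, ECG_CLASSES), function(cl)
      tryCatch(class_aggregate(sums, cl), error = function(e) NULL))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecgxai")),
    seed = config$seed,
    n_per_class = config$n_per_class,
    receptive_fields = c(short = specs$short$r, long = specs$long$r),
    hyperparameters = list(batch_size = config$batch_size,
                           learning_rate = config$learning_rate,
                           f_last = config$f_last, epochs = config$epochs),
    ensemble_weights = unclass(weights),
    methods = config$methods,
    test_metrics = test_metrics,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(auc_table, file.path(config$out_dir, "auc_table.csv"),
                     row.names = FALSE)
    for (cl in names(beat_summaries))
      if (!is.null(beat_summaries[[cl]]))
        write_beat_summary(beat_summaries[[cl]],
                           file.path(config$out_dir,
                                     sprintf("template_%s.csv",
                                             gsub("-", "", cl))))
  }
  list(specs = specs, fits = fits, ensemble = ens,
       test_metrics = test_metrics, auc_table = auc_table,
       beat_summaries = beat_summaries, manifest = manifest)
}
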