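# Configuration, file-format contracts and pipeline assembly. CSV is the
# interchange format for items, designs, schedules and choice tables; run
# configurations are flat YAML key-value files; manifests and reports are
# JSON.

run_config_defaults <- function() {
  list(
    # model parameters
    beta_conf = 0.01, cost = 0.01, beta_bias = 0,
    dt_ms = 10, deadline_ms = 5000,
    prior_variant = "empirical", precision_variant = "veridical",
    flat_lambda = 1e-6, default_confidence = 4.18,
    # synthetic-study design
    n_subjects = 30, n_items = 120, rating_mean = 5, rating_sd = 2,
    conf_probs = c(0.02, 0.05, 0.13, 0.31, 0.49),
    target_high = 40, target_medium = 40, target_low = 40, target_mixed = 120,
    delta_max = 1, integer_ratings = FALSE, conf_mode = "independent",
    # fitting
    grid_n = 30, grid_low = 0.001, grid_high = 0.1, n_reps = 30,
    seed = 1
  )
}

#' Load a run configuration
#'
#' Reads a flat YAML key-value file, applies the default for every absent
#' key, and validates the result. Unknown keys and constraint violations
#' are errors naming the offending key. An empty (or missing `path = NULL`)
#' configuration yields all defaults: dt 10 ms, 5 s deadline, empirical
#' prior, veridical precision, 30-point log grid on (0.001, 0.1), 30
#' repetitions.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config error: file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_keys <- c("beta_conf", "cost", "beta_bias", "dt_ms", "deadline_ms",
                "flat_lambda", "default_confidence", "n_subjects", "n_items",
                "rating_mean", "rating_sd", "target_high", "target_medium",
                "target_low", "target_mixed", "delta_max", "grid_n",
                "grid_low", "grid_high", "n_reps", "seed")
  for (k in num_keys)
    if (!is.numeric(cfg[[k]]))
      stop("config error: key '", k, "' must be numeric")
  # constructor validation covers the cross-field constraints
  tryCatch(as_model_params(cfg), error = function(e)
    stop("config error: ", conditionMessage(e), call. = FALSE))
  tryCatch(as_study_config(cfg), error = function(e)
    stop("config error: ", conditionMessage(e), call. = FALSE))
  if (cfg$grid_n < 1 || cfg$grid_low <= 0 || cfg$grid_low >= cfg$grid_high)
    stop("config error: grid must satisfy 0 < grid_low < grid_high, grid_n >= 1")
  if (cfg$n_reps < 1) stop("config error: n_reps must be >= 1")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @param path Destination YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Model parameters / study design from a run configuration
#' @param cfg A `run_config` list.
#' @return [model_params()] or [study_config()] respectively.
#' @export
as_model_params <- function(cfg) {
  model_params(beta_conf = cfg$beta_conf, cost = cfg$cost,
               beta_bias = cfg$beta_bias, dt_ms = cfg$dt_ms,
               deadline_ms = cfg$deadline_ms,
               prior_variant = cfg$prior_variant,
               precision_variant = cfg$precision_variant,
               flat_lambda = cfg$flat_lambda,
               default_confidence = cfg$default_confidence)
}

#' @rdname as_model_params
#' @export
as_study_config <- function(cfg) {
  study_config(n_subjects = cfg$n_subjects, n_items = cfg$n_items,
               rating_mean = cfg$rating_mean, rating_sd = cfg$rating_sd,
               conf_probs = cfg$conf_probs,
               targets = c(high = cfg$target_high, medium = cfg$target_medium,
                           low = cfg$target_low, mixed = cfg$target_mixed),
               delta_max = cfg$delta_max,
               integer_ratings = isTRUE(cfg$integer_ratings),
               conf_mode = cfg$conf_mode,
               seed = cfg$seed)
}

# --- CSV contracts ------------------------------------------------------

#' Read and write the tidy file formats
#'
#' Items: `item_id,rating,confidence` (confidence optional). Choice tables:
#' the exact `choice_table` columns. Schedules: one row per presentation
#' segment, `trial_id,segment_index,item_index,duration_ms`.
#'
#' @param x Object to write.
#' @param path CSV path.
#' @return The object read, or (invisibly) `path` for writers.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_choice_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_choice_table <- function(path) {
  x <- read.csv(path)
  need <- c("subject_id", "trial_id", "rep", "value_1", "value_2", "conf_1",
            "conf_2", "rel_value", "overall_value", "rel_duration_share",
            "first_item", "long_item", "choice", "rt_ms", "aborted")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed choice table, missing column(s): ",
         paste(miss, collapse = ", "))
  class(x) <- c("choice_table", "data.frame")
  x
}

#' @rdname table_io
#' @export
read_items <- function(path) {
  x <- read.csv(path)
  if (!all(c("item_id", "rating") %in% names(x)))
    stop("malformed items file: need columns item_id, rating")
  if (is.null(x$confidence)) x$confidence <- NA_real_
  x
}

#' @rdname table_io
#' @export
write_schedules <- function(specs, path) {
  rows <- do.call(rbind, lapply(specs, function(s) {
    seg <- s$schedule$segments
    data.frame(trial_id = s$trial_id, segment_index = seq_len(nrow(seg)),
               item_index = seg$item_index, duration_ms = seg$duration_ms)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(dir, config, inputs = character(0)) {
  manifest <- list(
    package = "bayeschoice",
    version = as.character(utils::packageVersion("bayeschoice")),
    config = unclass(config),
    input_hashes = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a generated study to a directory
#'
#' Serializes items, the trial design, per-trial schedules, the effective
#' configuration and a manifest so the study can be reloaded (or
#' regenerated bit-identically from the manifest's config and seed).
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @param config The `run_config` that produced the study.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  items <- do.call(rbind, study$items)
  write.csv(items, file.path(dir, "items.csv"), row.names = FALSE)
  write.csv(study$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write_schedules(study$specs, file.path(dir, "schedules.csv"))
  if (is.null(config)) {
    config <- validate_config(utils::modifyList(run_config_defaults(),
                                                study_config_keys(study$config)))
  }
  write_config(config, file.path(dir, "config.yaml"))
  write_manifest(dir, config,
                 file.path(dir, c("items.csv", "trials.csv", "schedules.csv")))
  invisible(dir)
}

study_config_keys <- function(sc) {
  list(n_subjects = sc$n_subjects, n_items = sc$n_items,
       rating_mean = sc$rating_mean, rating_sd = sc$rating_sd,
       conf_probs = sc$conf_probs,
       target_high = unname(sc$targets[["high"]]),
       target_medium = unname(sc$targets[["medium"]]),
       target_low = unname(sc$targets[["low"]]),
       target_mixed = unname(sc$targets[["mixed"]]),
       delta_max = sc$delta_max, integer_ratings = sc$integer_ratings,
       conf_mode = sc$conf_mode, seed = sc$seed)
}

#' Reload a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return A study list (`specs`, `items`, `trials`, `config`) equivalent
#'   to the [generate_study()] output it was written from.
#' @export
read_study <- function(dir) {
  items <- read_items(file.path(dir, "items.csv"))
  trials <- read.csv(file.path(dir, "trials.csv"))
  sched <- read.csv(file.path(dir, "schedules.csv"))
  cfg <- load_config(file.path(dir, "config.yaml"))
  params <- as_model_params(cfg)
  specs <- lapply(seq_len(nrow(trials)), function(j) {
    tr <- trials[j, ]
    seg <- sched[sched$trial_id == tr$trial_id, ]
    schedule <- structure(list(
      segments = data.frame(item_index = seg$item_index,
                            duration_ms = seg$duration_ms),
      long_item = tr$long_item, first_item = tr$first_item,
      dt_ms = params$dt_ms, deadline_ms = params$deadline_ms,
      long_mean = 500, short_mean = 200), class = "presentation_schedule")
    pair <- items[match(c(tr$item_1, tr$item_2), items$item_id), ]
    trial_spec(pair, schedule, trial_id = tr$trial_id,
               subject_id = tr$subject_id)
  })
  subj_prefix <- sub("_i.*", "", items$item_id)
  list(specs = specs,
       items = unname(split(items, factor(subj_prefix, unique(subj_prefix)))),
       trials = trials, config = as_study_config(cfg))
}

# --- pipeline -----------------------------------------------------------

#' Run a pipeline stage
#'
#' Dispatches the package's end-to-end commands: `synth` (generate and
#' write a study), `simulate` (run the model over a study directory),
#' `fit` (grid search against observed summary statistics), `analyze`
#' (signature regressions on a choice table), `sensitivity` (parameter
#' scan). Every output directory receives a manifest sufficient for
#' bit-identical re-runs.
#'
#' @param command One of `"synth"`, `"simulate"`, `"fit"`, `"analyze"`,
#'   `"sensitivity"`.
#' @param config A `run_config` (see [load_config()]).
#' @param studydir Study directory (input for `simulate`/`fit`/
#'   `sensitivity`, output of `synth`).
#' @param choices Path to a choice-table CSV (input for `fit`/`analyze`).
#' @param out Output file (`simulate`: choices CSV; `fit`/`analyze`: JSON;
#'   `sensitivity`: CSV).
#' @return Invisibly, the primary result object of the stage.
#' @export
run_pipeline <- function(command, config = load_config(),
                         studydir = NULL, choices = NULL, out = NULL) {
  command <- match.arg(command,
                       c("synth", "simulate", "fit", "analyze", "sensitivity"))
  params <- as_model_params(config)
  if (command == "synth") {
    stopifnot(!is.null(studydir))
    study <- generate_study(as_study_config(config), params)
    write_study(study, studydir, config)
    return(invisible(study))
  }
  if (command == "simulate") {
    stopifnot(!is.null(studydir), !is.null(out))
    study <- read_study(studydir)
    prior <- fit_prior(study_ratings(study), config$prior_variant,
                       config$flat_lambda)
    tab <- simulate_experiment(study$specs, prior, params,
                               n_reps = config$n_reps, seed = config$seed)
    write_choice_table(tab, out)
    return(invisible(tab))
  }
  if (command == "fit") {
    stopifnot(!is.null(studydir), !is.null(choices), !is.null(out))
    study <- read_study(studydir)
    observed <- read_choice_table(choices)
    target <- summary_stats(observed)
    prior <- fit_prior(study_ratings(study), config$prior_variant,
                       config$flat_lambda)
    fit <- grid_search(study$specs, prior, target, params,
                       grid = make_grid(config$grid_n, config$grid_low,
                                        config$grid_high),
                       n_reps = config$n_reps, seed = config$seed)
    jsonlite::write_json(
      list(best = fit$best_params, loss = fit$losses[fit$best_index],
           target_stats = fit$target_stats[c("accuracy", "median_rt_ms")],
           achieved_stats = fit$achieved_stats[c("accuracy", "median_rt_ms")],
           grid = fit$grid, losses = fit$losses),
      out, auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }
  if (command == "analyze") {
    stopifnot(!is.null(choices), !is.null(out))
    tab <- read_choice_table(choices)
    ct <- choice_regression(tab)
    rt <- rt_regression(tab)
    flags <- qualitative_signature(list(main = tab))
    cross <- tryCatch(crossover_value(ct), error = function(e) NA_real_)
    jsonlite::write_json(
      list(choice_coefficients = ct, rt_coefficients = rt,
           crossover_value = cross, flags = flags),
      out, auto_unbox = TRUE, digits = NA)
    return(invisible(flags))
  }
  # sensitivity
  stopifnot(!is.null(studydir), !is.null(out))
  study <- read_study(studydir)
  vals <- exp(seq(log(config$grid_low), log(config$grid_high),
                  length.out = min(config$grid_n, 5)))
  scan <- sensitivity_scan(study, vals, vals,
                           variants = c("main", "flat_prior"),
                           params_template = params,
                           n_reps = config$n_reps, seed = config$seed)
  write.csv(scan, out, row.names = FALSE)
  invisible(scan)
}
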