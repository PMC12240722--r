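# Shared fixtures: tiny hand-built schedules, items and studies.

# Fixed schedule from explicit segments (no RNG), for hand-walk tests.
manual_schedule <- function(segments_items, segments_ms, long_item = 1L,
                            first_item = segments_items[1], dt_ms = 10,
                            deadline_ms = sum(segments_ms),
                            long_mean = 500, short_mean = 200) {
  structure(list(
    segments = data.frame(item_index = as.integer(segments_items),
                          duration_ms = segments_ms),
    long_item = as.integer(long_item), first_item = as.integer(first_item),
    dt_ms = dt_ms, deadline_ms = deadline_ms,
    long_mean = long_mean, short_mean = short_mean),
    class = "presentation_schedule")
}

pair_items <- function(v1, v2, c1 = 4, c2 = 4) {
  data.frame(item_id = c("a", "b"), rating = c(v1, v2), confidence = c(c1, c2))
}

# A pair spec with a freshly drawn schedule.
quick_spec <- function(v1 = 6, v2 = 4, c1 = 4, c2 = 4, long_item = 1L,
                       first_item = 1L, trial_id = 1L, subject_id = 1L,
                       params = model_params()) {
  sch <- generate_schedule(long_item = long_item, first_item = first_item,
                           dt_ms = params$dt_ms,
                           deadline_ms = params$deadline_ms)
  trial_spec(pair_items(v1, v2, c1, c2), sch, trial_id = trial_id,
             subject_id = subject_id)
}

# Small study for integration-style tests.
quick_study <- function(n_subjects = 2, seed = 7,
                        targets = c(high = 5, medium = 5, low = 5, mixed = 15),
                        n_items = 40) {
  generate_study(study_config(n_subjects = n_subjects, n_items = n_items,
                              targets = targets, seed = seed))
}

# Simulate one variant of the model over a study (shared substreams).
variant_table <- function(study, variant = "main", params = model_params(),
                          n_reps = 1, seed = 1L, beta_bias = 0.04) {
  ratings <- study_ratings(study)
  p <- params
  if (variant == "zero_prior") p$prior_variant <- "zero"
  if (variant == "flat_prior") p$prior_variant <- "flat"
  if (variant == "equal_weight") p$precision_variant <- "equal_weight"
  if (variant == "biased") { p$precision_variant <- "biased"; p$beta_bias <- beta_bias }
  pv <- switch(p$prior_variant, empirical = "empirical", zero = "zero", flat = "flat")
  prior <- fit_prior(ratings, pv, p$flat_lambda)
  simulate_experiment(study$specs, prior, p, n_reps = n_reps, seed = seed)
}
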