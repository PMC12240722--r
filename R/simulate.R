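# Trial and experiment simulation: sample per the presentation schedule,
# update beliefs, assess stopping after every sample, decide, record RT.

#' Construct a trial specification
#'
#' @param items Data frame of exactly two rows with columns `item_id`,
#'   `rating` (0-10) and optionally `confidence` (1-5; `NA` allowed).
#' @param schedule A [generate_schedule()] object covering the deadline.
#' @param trial_id,subject_id Identifiers carried into the choice table.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(items, schedule, trial_id = 1L, subject_id = 1L) {
  stopifnot(is.data.frame(items), nrow(items) == 2,
            all(c("item_id", "rating") %in% names(items)),
            inherits(schedule, "presentation_schedule"))
  if (any(items$rating < 0 | items$rating > 10))
    stop("invalid parameter: ratings must lie in [0, 10]")
  if (is.null(items$confidence)) items$confidence <- NA_real_
  structure(list(items = items, schedule = schedule,
                 trial_id = trial_id, subject_id = subject_id),
            class = "trial_spec")
}

# Per-trial static quantities shared by the C++ kernel and the R reference
# loop. mean_conf is the average confidence over the item context (used by
# the equal-weight variant).
trial_inputs <- function(spec, prior, params, mean_conf = NULL) {
  conf <- spec$items$confidence
  if (is.null(mean_conf)) {
    cc <- conf
    cc[is.na(cc)] <- params$default_confidence
    mean_conf <- mean(cc)
  }
  list(
    v = spec$items$rating,
    tau_samp = effective_precision(conf, params, "sampling"),
    tau_upd = effective_precision(conf, params, "updating", mean_conf = mean_conf),
    shares = c(duration_share(spec$schedule, 1L), duration_share(spec$schedule, 2L)),
    cap = as.integer(params$deadline_ms / params$dt_ms)
  )
}

#' Simulate one choice trial
#'
#' Runs the sequential-sampling loop: at step `t` the attended item yields a
#' noisy value sample (sampling precision), its posterior is updated
#' (assumed updating precision), and the value of additional computation is
#' assessed. The first sample is always taken before the first stopping
#' assessment. On stop, the item with the larger posterior mean is chosen
#' and `rt_ms = t * dt_ms`; trials that reach the deadline still wanting to
#' sample are aborted with no choice.
#'
#' @param spec A [trial_spec()].
#' @param prior A [fit_prior()] object.
#' @param params A [model_params()] object.
#' @param mean_conf Average confidence across the item context (equal-weight
#'   variant); defaults to the mean of the trial's two items.
#' @param engine `"cpp"` (compiled kernel) or `"r"` (reference loop built
#'   from the exported primitives; identical draws under a shared seed).
#' @param trace If `TRUE` (implies the R engine), record every stopping
#'   assessment; the result gains a `voc_trace` data frame with columns
#'   `step`, `h`, `net_value` for debugging the stopping rule.
#' @return An object of class `trial_result` with `choice` (`NA` if
#'   aborted), `rt_ms`, `n_samples`, `aborted`, and the two final
#'   `posterior_state`s in `states`.
#' @export
simulate_trial <- function(spec, prior, params, mean_conf = NULL,
                           engine = c("cpp", "r"), trace = FALSE) {
  engine <- if (trace) "r" else match.arg(engine)
  stopifnot(inherits(spec, "trial_spec"), inherits(prior, "prior_belief"),
            inherits(params, "model_params"))
  inp <- trial_inputs(spec, prior, params, mean_conf)
  att <- attended_steps(spec$schedule, inp$cap)
  res <- if (engine == "cpp") {
    sim_trial_cpp(inp$v, inp$tau_samp, inp$tau_upd,
                  prior$mu_prior, prior$lambda_prior,
                  params$cost, params$dt_ms, inp$cap, att, inp$shares)
  } else {
    sim_trial_r(inp, prior, params, att, trace = trace)
  }
  states <- lapply(1:2, function(i) {
    s <- posterior_init(prior)
    s$n_samples <- as.integer(res$n[i])
    s$sample_mean <- if (res$n[i] > 0) res$sample_mean[i] else NA_real_
    s$mu <- res$mu[i]; s$lam <- res$lam[i]
    s
  })
  structure(list(
    choice = if (is.na(res$choice)) NA_integer_ else as.integer(res$choice),
    rt_ms = if (res$aborted) NA_real_ else res$n_samples * params$dt_ms,
    n_samples = as.integer(res$n_samples),
    aborted = isTRUE(res$aborted),
    states = states,
    voc_trace = res$voc_trace,
    trial_id = spec$trial_id, subject_id = spec$subject_id
  ), class = "trial_result")
}

# Reference loop over the exported primitives; consumes the same RNG stream
# as the compiled kernel (one Gaussian draw per step).
sim_trial_r <- function(inp, prior, params, att, trace = FALSE) {
  states <- list(posterior_init(prior), posterior_init(prior))
  stopped <- FALSE
  t <- 0L
  traces <- if (trace) list() else NULL
  while (t < inp$cap) {
    t <- t + 1L
    i <- att[t]
    x <- draw_sample(inp$v[i], inp$tau_samp[i], n = 1L)
    states[[i]] <- update_posterior(states[[i]], x, inp$tau_upd[i])
    remaining <- inp$cap - t
    if (remaining < 1L) break
    voc <- assess_voc(states, params, inp$shares, inp$tau_upd, remaining)
    if (trace)
      traces[[t]] <- data.frame(step = t, h = voc$horizons,
                                net_value = voc$net_values)
    if (voc$stop) { stopped <- TRUE; break }
  }
  list(
    voc_trace = if (trace) do.call(rbind, traces) else NULL,
    choice = if (stopped) decide(states) else NA_integer_,
    n_samples = t, aborted = !stopped,
    n = vapply(states, `[[`, numeric(1), "n_samples"),
    sample_mean = vapply(states, `[[`, numeric(1), "sample_mean"),
    mu = vapply(states, `[[`, numeric(1), "mu"),
    lam = vapply(states, `[[`, numeric(1), "lam"))
}

# Deterministic per-(trial, rep) substream seed below 2^31, so trials are
# reproducible in isolation and independent of execution order.
substream_seed <- function(seed, trial, rep) {
  as.integer((as.numeric(seed %% 1000003L) * 7919 + trial * 1009 + rep * 101) %%
               2147483629) + 1L
}

#' Simulate a full experiment into a tidy choice table
#'
#' Each trial spec is simulated `n_reps` times on an independent random
#' substream keyed by (trial index, repetition), so results do not depend on
#' execution order. Aborted trials are retained but flagged. The average
#' confidence used by the equal-weight variant is taken over all unique
#' items in `specs`.
#'
#' @param specs List of [trial_spec()] objects.
#' @param prior A [fit_prior()] object.
#' @param params A [model_params()] object.
#' @param n_reps Repetitions per trial (>= 1).
#' @param seed Root seed for the per-trial substreams.
#' @return A `choice_table` data frame with columns `subject_id`,
#'   `trial_id`, `rep`, `value_1`, `value_2`, `conf_1`, `conf_2`,
#'   `rel_value`, `overall_value`, `rel_duration_share`, `first_item`,
#'   `long_item`, `choice`, `rt_ms`, `aborted`.
#' @export
simulate_experiment <- function(specs, prior, params, n_reps = 30, seed = 1L) {
  stopifnot(length(specs) >= 1, n_reps >= 1)
  items_all <- do.call(rbind, lapply(specs, function(s)
    s$items[, c("item_id", "rating", "confidence")]))
  items_all <- items_all[!duplicated(items_all$item_id), ]
  cc <- items_all$confidence
  cc[is.na(cc)] <- params$default_confidence
  mean_conf <- mean(cc)

  n_trials <- length(specs)
  pre <- lapply(specs, function(s) {
    inp <- trial_inputs(s, prior, params, mean_conf)
    list(inp = inp, att = attended_steps(s$schedule, inp$cap))
  })

  n_rows <- n_trials * n_reps
  choice <- integer(n_rows); nsamp <- integer(n_rows); abrt <- logical(n_rows)
  k <- 0L
  for (ti in seq_len(n_trials)) {
    p <- pre[[ti]]
    tkey <- specs[[ti]]$trial_id
    if (!is.numeric(tkey)) tkey <- ti
    for (r in seq_len(n_reps)) {
      set.seed(substream_seed(seed, tkey, r))
      res <- sim_trial_cpp(p$inp$v, p$inp$tau_samp, p$inp$tau_upd,
                           prior$mu_prior, prior$lambda_prior,
                           params$cost, params$dt_ms, p$inp$cap,
                           p$att, p$inp$shares)
      k <- k + 1L
      choice[k] <- if (is.na(res$choice)) NA_integer_ else as.integer(res$choice)
      nsamp[k] <- res$n_samples
      abrt[k] <- isTRUE(res$aborted)
    }
  }
  idx <- rep(seq_len(n_trials), each = n_reps)
  v1 <- vapply(specs, function(s) s$items$rating[1], numeric(1))[idx]
  v2 <- vapply(specs, function(s) s$items$rating[2], numeric(1))[idx]
  c1 <- vapply(specs, function(s) as.numeric(s$items$confidence[1]), numeric(1))[idx]
  c2 <- vapply(specs, function(s) as.numeric(s$items$confidence[2]), numeric(1))[idx]
  out <- data.frame(
    subject_id = vapply(specs, function(s) s$subject_id, numeric(1))[idx],
    trial_id = vapply(specs, function(s) s$trial_id, numeric(1))[idx],
    rep = rep(seq_len(n_reps), times = n_trials),
    value_1 = v1, value_2 = v2, conf_1 = c1, conf_2 = c2,
    rel_value = v1 - v2, overall_value = (v1 + v2) / 2,
    rel_duration_share = vapply(pre, function(p) p$inp$shares[1], numeric(1))[idx],
    first_item = vapply(specs, function(s) s$schedule$first_item, integer(1))[idx],
    long_item = vapply(specs, function(s) s$schedule$long_item, integer(1))[idx],
    choice = choice,
    rt_ms = ifelse(abrt, NA_real_, nsamp * params$dt_ms),
    aborted = abrt)
  class(out) <- c("choice_table", "data.frame")
  out
}

#' Summary statistics used for model fitting
#'
#' Accuracy is the proportion of non-aborted, unequal-value trials in which
#' the higher-rated item was chosen (choice consistency with the initial
#' ratings); median RT is taken over non-aborted trials, in ms. Aborted
#' trials are excluded from both, as are equal-value trials from accuracy.
#'
#' @param table A `choice_table`.
#' @return List with `accuracy`, `median_rt_ms`, `n_used`, `abort_rate`.
#' @export
summary_stats <- function(table) {
  ok <- !table$aborted & !is.na(table$choice)
  if (!any(ok))
    stop("insufficient data: no non-aborted trials")
  d <- table[ok, ]
  uneq <- d$value_1 != d$value_2
  if (!any(uneq))
    stop("insufficient data: no unequal-value trials for accuracy")
  better <- ifelse(d$value_1[uneq] > d$value_2[uneq], 1L, 2L)
  list(accuracy = mean(d$choice[uneq] == better),
       median_rt_ms = median(d$rt_ms),
       n_used = nrow(d),
       abort_rate = mean(table$aborted))
}
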