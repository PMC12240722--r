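# Synthetic-study generator: items with ratings and confidence, rank-based
# choice-set construction (high / medium / low matched-value pairs plus
# mixed pairs spanning the value-difference range), and presentation
# schedules with value-independent long/first assignment.

#' Configuration for a synthetic study
#'
#' Defaults emulate a standard two-alternative forced-choice design: 30
#' subjects, items rated 0-10 with confidence 1-5, and per-subject choice
#' sets targeting 40 high-, 40 medium-, 40 low-value matched pairs plus 120
#' mixed pairs (240 trials).
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_items Items rated per subject (>= 8).
#' @param rating_mean,rating_sd Gaussian rating distribution on the 0-10
#'   scale (draws are clipped to the scale).
#' @param conf_probs Probabilities for confidence levels 1..5. The default
#'   puts most mass on 4-5 (mean 4.2), matching the high average confidence
#'   typical of consumer-item rating tasks.
#' @param conf_mode `"independent"` (default: confidence drawn independently
#'   of rating) or `"u_shaped"` (confidence tilted upward for extreme
#'   ratings, mimicking the U-shaped confidence-value relation seen in
#'   rating data; implemented by exponentially tilting `conf_probs` with
#'   the item's standardized distance from the rating mean).
#' @param targets Named trial-count targets `high`, `medium`, `low`,
#'   `mixed`.
#' @param delta_max Maximum |rating difference| for a matched
#'   (high/medium/low) pair; implements "zero or close to zero value
#'   difference".
#' @param integer_ratings If `TRUE`, ratings are rounded to whole scale
#'   points, mimicking the human response format. Default `FALSE`
#'   (continuous), since the model operates on continuous values.
#' @param seed Root seed recorded in the manifest.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 30, n_items = 120,
                         rating_mean = 5, rating_sd = 2,
                         conf_probs = c(0.02, 0.05, 0.13, 0.31, 0.49),
                         targets = c(high = 40, medium = 40, low = 40, mixed = 120),
                         delta_max = 1, integer_ratings = FALSE,
                         conf_mode = c("independent", "u_shaped"), seed = 1L) {
  conf_mode <- match.arg(conf_mode)
  stopifnot(n_subjects >= 1, n_items >= 8, rating_sd > 0,
            length(conf_probs) == 5, all(conf_probs >= 0), sum(conf_probs) > 0,
            all(c("high", "medium", "low", "mixed") %in% names(targets)),
            all(targets >= 0), delta_max > 0)
  structure(list(n_subjects = n_subjects, n_items = n_items,
                 rating_mean = rating_mean, rating_sd = rating_sd,
                 conf_probs = conf_probs / sum(conf_probs),
                 targets = targets, delta_max = delta_max,
                 integer_ratings = integer_ratings, conf_mode = conf_mode,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate one subject's item set
#'
#' Ratings are drawn from a Gaussian clipped to `[0, 10]`; confidence
#' levels are drawn from the configured categorical distribution,
#' independent of rating.
#'
#' @param config A [study_config()].
#' @param subject_id Identifier prefixed to item ids.
#' @return Data frame with `item_id`, `rating`, `confidence`.
#' @export
generate_items <- function(config, subject_id = 1L) {
  r <- pmin(10, pmax(0, rnorm(config$n_items, config$rating_mean, config$rating_sd)))
  if (config$integer_ratings) r <- round(r)
  conf <- if (identical(config$conf_mode, "u_shaped")) {
    # exponential tilt toward high confidence for extreme ratings
    e <- abs(r - config$rating_mean) / config$rating_sd
    vapply(e, function(ei) {
      w <- config$conf_probs * exp(0.5 * (1:5) * ei)
      sample(1:5, 1, prob = w / sum(w))
    }, integer(1))
  } else {
    sample(1:5, config$n_items, replace = TRUE, prob = config$conf_probs)
  }
  data.frame(
    item_id = sprintf("s%s_i%03d", subject_id, seq_len(config$n_items)),
    rating = r,
    confidence = conf)
}

#' Build choice sets from rated items
#'
#' Pairs are sorted into conditions by rank-ordered rating: high, medium
#' and low pairs are drawn from the top, middle and bottom thirds of the
#' rating distribution with |rating difference| <= `delta_max`; mixed pairs
#' span the full value-difference range (stratified over quartiles of
#' |difference|). No unordered pair repeats. If the item set cannot fill a
#' target, the shortfall is reported via a warning and the available pairs
#' are used, mirroring the variable trial counts of human studies.
#'
#' @param items Data frame from [generate_items()].
#' @param targets Named counts `high`, `medium`, `low`, `mixed`.
#' @param delta_max Matched-pair rating tolerance.
#' @return Data frame with `item_1`, `item_2` (row indices into `items`),
#'   and `condition`.
#' @export
build_choice_sets <- function(items, targets = c(high = 40, medium = 40,
                                                 low = 40, mixed = 120),
                              delta_max = 1) {
  n <- nrow(items)
  stopifnot(n >= 8)
  rk <- rank(items$rating, ties.method = "first")
  tercile <- cut(rk, breaks = c(0, n / 3, 2 * n / 3, n),
                 labels = c("low", "medium", "high"))
  pairs <- t(utils::combn(n, 2))
  dv <- abs(items$rating[pairs[, 1]] - items$rating[pairs[, 2]])
  same_terc <- as.character(tercile[pairs[, 1]]) == as.character(tercile[pairs[, 2]])
  used <- rep(FALSE, nrow(pairs))
  out <- list()

  take <- function(idx, k, cond) {
    idx <- idx[!used[idx]]
    if (length(idx) < k) {
      warning(sprintf("choice-set shortfall: %s condition filled %d of %d",
                      cond, length(idx), k), call. = FALSE)
      k <- length(idx)
    }
    sel <- if (k > 0) sample(idx, k) else integer(0)
    used[sel] <<- TRUE
    if (k > 0) data.frame(item_1 = pairs[sel, 1], item_2 = pairs[sel, 2],
                          condition = cond) else NULL
  }

  for (cond in c("high", "medium", "low")) {
    elig <- which(same_terc & as.character(tercile[pairs[, 1]]) == cond &
                    dv <= delta_max)
    out[[cond]] <- take(elig, targets[[cond]], cond)
  }
  # mixed: stratify remaining pairs over quartiles of |rating difference|
  rem <- which(!used)
  k_mixed <- targets[["mixed"]]
  if (length(rem) > 0 && k_mixed > 0) {
    qs <- stats::quantile(dv[rem], probs = c(0.25, 0.5, 0.75))
    bin <- findInterval(dv[rem], qs) + 1L
    per_bin <- diff(round(seq(0, k_mixed, length.out = 5)))
    sel <- unlist(lapply(1:4, function(b) {
      idx <- rem[bin == b]
      sample(idx, min(length(idx), per_bin[b]))
    }))
    short <- k_mixed - length(sel)
    if (short > 0) {
      extra <- setdiff(rem, sel)
      sel <- c(sel, sample(extra, min(length(extra), short)))
    }
    if (length(sel) < k_mixed)
      warning(sprintf("choice-set shortfall: mixed condition filled %d of %d",
                      length(sel), k_mixed), call. = FALSE)
    out[["mixed"]] <- data.frame(item_1 = pairs[sel, 1], item_2 = pairs[sel, 2],
                                 condition = "mixed")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # randomize which item of the pair is labelled first
  flip <- sample(c(TRUE, FALSE), nrow(res), replace = TRUE)
  tmp <- res$item_1[flip]
  res$item_1[flip] <- res$item_2[flip]
  res$item_2[flip] <- tmp
  res
}

#' Generate a complete synthetic study
#'
#' For each subject: items, choice sets, and a presentation schedule per
#' trial with `long_item` and `first_item` assigned by independent fair
#' coin flips (value-independent, as in an exogenous attention
#' manipulation). Fully determined by `config$seed`.
#'
#' @param config A [study_config()].
#' @param params A [model_params()] supplying `dt_ms` and `deadline_ms` for
#'   the schedules.
#' @return List with `specs` (list of [trial_spec()]), `items` (one data
#'   frame per subject), `trials` (design table: `subject_id`, `trial_id`,
#'   `item_1`, `item_2`, `condition`, `first_item`, `long_item`), and
#'   `config`.
#' @export
generate_study <- function(config, params = model_params()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  specs <- list()
  items_by_subject <- vector("list", config$n_subjects)
  trials <- list()
  tid <- 0L
  for (s in seq_len(config$n_subjects)) {
    items <- generate_items(config, subject_id = s)
    items_by_subject[[s]] <- items
    sets <- build_choice_sets(items, config$targets, config$delta_max)
    tid0 <- tid
    for (j in seq_len(nrow(sets))) {
      tid <- tid + 1L
      long_item <- sample(1:2, 1)
      first_item <- sample(1:2, 1)
      sch <- generate_schedule(long_item = long_item, first_item = first_item,
                               dt_ms = params$dt_ms,
                               deadline_ms = params$deadline_ms)
      i1 <- sets$item_1[j]; i2 <- sets$item_2[j]
      pair <- structure(list(item_id = items$item_id[c(i1, i2)],
                             rating = items$rating[c(i1, i2)],
                             confidence = items$confidence[c(i1, i2)]),
                        class = "data.frame", row.names = 1:2)
      specs[[tid]] <- structure(list(items = pair, schedule = sch,
                                     trial_id = tid, subject_id = s),
                                class = "trial_spec")
    }
    trials[[s]] <- data.frame(
      subject_id = s, trial_id = (tid0 + 1L):tid,
      item_1 = items$item_id[sets$item_1], item_2 = items$item_id[sets$item_2],
      condition = sets$condition,
      first_item = vapply(specs[(tid0 + 1L):tid],
                          function(x) x$schedule$first_item, integer(1)),
      long_item = vapply(specs[(tid0 + 1L):tid],
                         function(x) x$schedule$long_item, integer(1)))
  }
  list(specs = specs, items = items_by_subject,
       trials = do.call(rbind, trials), config = config)
}

#' Pooled ratings across a study's subjects
#'
#' Convenience accessor for fitting the context prior to everything the
#' simulated raters produced.
#'
#' @param study A [generate_study()] result.
#' @return Numeric vector of all ratings.
#' @export
study_ratings <- function(study) {
  unlist(lapply(study$items, `[[`, "rating"), use.names = FALSE)
}
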