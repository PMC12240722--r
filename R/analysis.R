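# Regression-based behavioral signatures on simulated choice tables:
# fixed-effects logistic / linear regressions with subject indicator
# intercepts and standardized predictors, the crossover point of the
# attention effect, qualitative sign-pattern flags per model variant, and a
# parameter-grid sensitivity scan.

# Adds standardized predictor columns; records centers/scales for mapping
# coefficients back to rating units. Population SD, so estimates are
# invariant to duplicating the dataset.
standardize_predictors <- function(d, vars) {
  scaling <- list()
  for (v in vars) {
    x <- d[[v]]
    s <- sqrt(mean((x - mean(x))^2))
    if (is.na(s) || s == 0) {
      d[[v]] <- x - mean(x)  # constant column: centered, slope will be 0/NA
      scaling[[v]] <- list(center = mean(x), scale = 1)
    } else {
      scaling[[v]] <- list(center = mean(x), scale = s)
      d[[v]] <- (x - mean(x)) / s
    }
  }
  attr(d, "scaling") <- scaling
  d
}

analysis_frame <- function(table) {
  d <- table[!table$aborted & !is.na(table$choice), , drop = FALSE]
  d <- as.data.frame(d)
  d$choose1 <- as.integer(d$choice == 1L)
  d$rel_duration <- d$rel_duration_share
  d$abs_value_diff <- abs(d$rel_value)
  if (!all(is.na(d$conf_1))) {
    d$rel_conf <- d$conf_1 - d$conf_2
    d$overall_conf <- (d$conf_1 + d$conf_2) / 2
  }
  d$subject <- factor(d$subject_id)
  d
}

# Subject indicator intercepts; a single-subject table gets a plain
# intercept (a one-level factor cannot be contrast-coded).
subject_term <- function(d) {
  if (nlevels(d$subject) >= 2) "0 + subject" else "1"
}

coef_table <- function(fit, drop_prefix = "subject|\\(Intercept\\)") {
  cf <- suppressWarnings(summary(fit)$coefficients)
  keep <- !grepl(paste0("^", drop_prefix), rownames(cf))
  cf <- cf[keep, , drop = FALSE]
  if (any(is.na(cf[, 1])))
    stop("singular fit: coefficient undefined for ",
         paste(rownames(cf)[is.na(cf[, 1])], collapse = ", "))
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             z = cf[, 3], row.names = NULL)
}

#' Logistic regression of choice on design predictors
#'
#' Fits a maximum-likelihood logistic regression of choosing the first item
#' with subject indicator intercepts. Predictors are standardized within
#' the dataset; interaction terms are products of the standardized main
#' effects. The default predictor set is relative value, relative
#' presentation duration (share of time the first item was on screen),
#' overall value and the duration-by-overall-value interaction; when the
#' table carries confidence ratings, relative confidence, overall
#' confidence and their value interactions are added.
#'
#' @param table A `choice_table` (aborted trials are excluded).
#' @param terms Character vector of model terms over the standardized
#'   predictors `rel_value`, `rel_duration`, `overall_value`, `rel_conf`,
#'   `overall_conf` (interactions via `":"`). `NULL` for the default set.
#' @return Data frame with `term`, `estimate`, `se`, `z` (subject
#'   intercepts omitted); predictor centers/scales in
#'   `attr(, "scaling")`.
#' @export
choice_regression <- function(table, terms = NULL) {
  d <- analysis_frame(table)
  if (nrow(d) < 2 || length(unique(d$choose1)) < 2)
    stop("insufficient data: need both choice outcomes")
  has_conf <- !is.null(d$rel_conf) && sd(c(d$conf_1, d$conf_2)) > 0
  if (is.null(terms)) {
    terms <- c("rel_value", "rel_duration", "overall_value",
               "rel_duration:overall_value")
    if (has_conf)
      terms <- c(terms, "rel_conf", "overall_conf",
                 "rel_conf:overall_value", "overall_conf:rel_value")
  }
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(d))
  if (length(missing_vars))
    stop("singular fit: predictor absent from table: ",
         paste(missing_vars, collapse = ", "))
  d <- standardize_predictors(d, vars)
  f <- stats::as.formula(paste("choose1 ~", subject_term(d), "+",
                               paste(terms, collapse = " + ")))
  fit <- suppressWarnings(glm(f, data = d, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-10,
                                                           maxit = 100)))
  out <- coef_table(fit)
  attr(out, "scaling") <- attr(d, "scaling")
  out
}

#' Linear regression of log response time on design predictors
#'
#' Ordinary least squares on `log(rt_ms)` with subject indicator intercepts
#' and standardized predictors. Defaults to absolute value difference and
#' overall value, plus overall confidence when available.
#'
#' @inheritParams choice_regression
#' @return Data frame with `term`, `estimate`, `se`, `z` (the t statistic).
#' @export
rt_regression <- function(table, terms = NULL) {
  d <- analysis_frame(table)
  if (nrow(d) < 2) stop("insufficient data: need at least 2 trials")
  has_conf <- !is.null(d$overall_conf) && sd(c(d$conf_1, d$conf_2)) > 0
  if (is.null(terms)) {
    terms <- c("abs_value_diff", "overall_value")
    if (has_conf) terms <- c(terms, "overall_conf")
  }
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  d <- standardize_predictors(d, vars)
  d$log_rt <- log(d$rt_ms)
  f <- stats::as.formula(paste("log_rt ~", subject_term(d), "+",
                               paste(terms, collapse = " + ")))
  fit <- suppressWarnings(lm(f, data = d))
  out <- coef_table(fit)
  attr(out, "scaling") <- attr(d, "scaling")
  out
}

#' Crossover point of the attention effect
#'
#' The overall-value level at which the effect of relative presentation
#' duration on choice is zero: `-b_duration / b_interaction` in
#' standardized units, mapped back to rating units via the recorded
#' centering and scaling of `overall_value`. Under the model this point
#' corresponds to the prior mean.
#'
#' @param coefs A [choice_regression()] coefficient table containing
#'   `rel_duration` and its interaction with `overall_value`.
#' @return Crossover point in rating units.
#' @export
crossover_value <- function(coefs) {
  sc <- attr(coefs, "scaling")
  b_main <- coefs$estimate[coefs$term == "rel_duration"]
  b_int <- coefs$estimate[canon_term(coefs$term) ==
                            canon_term("rel_duration:overall_value")]
  if (length(b_main) != 1 || length(b_int) != 1)
    stop("undefined crossover: duration terms missing from coefficient table")
  if (abs(b_int) < 1e-8)
    stop("undefined crossover: interaction coefficient is (near) zero")
  z <- -b_main / b_int
  sc$overall_value$center + sc$overall_value$scale * z
}

# --- qualitative signature flags ---------------------------------------

# Interaction labels are order-insensitive ("a:b" matches "b:a", as glm may
# reorder components by appearance in the formula).
canon_term <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), character(1))
}

term_z <- function(ct, term) {
  z <- ct$z[canon_term(ct$term) == canon_term(term)]
  if (length(z) != 1)
    stop("term '", term, "' not present exactly once in coefficient table")
  z
}

sig_row <- function(variant, flag, value, holds) {
  data.frame(variant = variant, flag = flag, value = value, holds = holds)
}

pos_sig <- function(ct, term, z_crit) {
  z <- term_z(ct, term)
  sig_row(NA_character_, term, z, z >= z_crit)
}
neg_sig <- function(ct, term, z_crit) {
  z <- term_z(ct, term)
  sig_row(NA_character_, term, z, z <= -z_crit)
}
null_eff <- function(ct, term, z_crit) {
  z <- term_z(ct, term)
  sig_row(NA_character_, term, z, abs(z) < z_crit)
}

#' Qualitative signature flags per model variant
#'
#' Evaluates the sign patterns that distinguish the model variants on a
#' common design. For the main (veridical, empirical-prior) model: positive
#' duration-by-overall-value interaction with a null duration main effect
#' (the reference-dependent attention effect), positive
#' confidence-by-value interactions, and faster RT / higher consistency
#' with overall confidence. Zero prior: a positive duration main effect.
#' Flat prior: both duration terms null. Equal-weight updating: null
#' relative-confidence terms and *slower* RT with overall confidence.
#' Biased confidence (overconfident vs baseline): lower accuracy and faster
#' median RT than the matched unbiased run.
#'
#' @param tables Named list of `choice_table`s on the same design; names
#'   among `"main"`, `"zero_prior"`, `"flat_prior"`, `"equal_weight"`,
#'   `"biased"`. The biased flags compare against the `"main"` table.
#' @param z_crit Two-sided z criterion (default 1.96).
#' @return Data frame with `variant`, `flag`, `value`, `holds`.
#' @export
qualitative_signature <- function(tables, z_crit = 1.96) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  nr <- vapply(tables, nrow, integer(1))
  if (length(unique(nr)) != 1)
    stop("incompatible tables: variants must share one design")
  out <- list()
  add <- function(variant, flag, row) {
    row$variant <- variant; row$flag <- flag
    out[[length(out) + 1L]] <<- row
  }

  if (!is.null(tables$main)) {
    ct <- choice_regression(tables$main)
    rt <- rt_regression(tables$main)
    add("main", "dur_x_overall_value_pos",
        pos_sig(ct, "rel_duration:overall_value", z_crit))
    add("main", "dur_main_null", null_eff(ct, "rel_duration", z_crit))
    if (canon_term("rel_conf:overall_value") %in% canon_term(ct$term)) {
      add("main", "relconf_x_overall_value_pos",
          pos_sig(ct, "rel_conf:overall_value", z_crit))
      add("main", "overallconf_x_rel_value_pos",
          pos_sig(ct, "overall_conf:rel_value", z_crit))
      add("main", "overallconf_rt_neg", neg_sig(rt, "overall_conf", z_crit))
      add("main", "overallconf_consistency_pos",
          consistency_slope(tables$main, z_crit, positive = TRUE))
    }
  }
  if (!is.null(tables$zero_prior)) {
    ct <- choice_regression(tables$zero_prior)
    add("zero_prior", "dur_main_pos", pos_sig(ct, "rel_duration", z_crit))
  }
  if (!is.null(tables$flat_prior)) {
    ct <- choice_regression(tables$flat_prior)
    add("flat_prior", "dur_main_null", null_eff(ct, "rel_duration", z_crit))
    add("flat_prior", "dur_x_overall_value_null",
        null_eff(ct, "rel_duration:overall_value", z_crit))
  }
  if (!is.null(tables$equal_weight)) {
    ct <- choice_regression(tables$equal_weight)
    rt <- rt_regression(tables$equal_weight)
    add("equal_weight", "relconf_x_overall_value_null",
        null_eff(ct, "rel_conf:overall_value", z_crit))
    add("equal_weight", "overallconf_rt_pos", pos_sig(rt, "overall_conf", z_crit))
  }
  if (!is.null(tables$biased)) {
    if (is.null(tables$main))
      stop("incompatible tables: biased flags need the matched 'main' baseline")
    sb <- summary_stats(tables$biased)
    s0 <- summary_stats(tables$main)
    add("biased", "accuracy_lower",
        sig_row(NA, NA, sb$accuracy - s0$accuracy, sb$accuracy < s0$accuracy))
    add("biased", "median_rt_faster",
        sig_row(NA, NA, sb$median_rt_ms - s0$median_rt_ms,
                sb$median_rt_ms < s0$median_rt_ms))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("variant", "flag", "value", "holds")]
}

# Choice consistency (choosing the higher-rated item) as a function of
# overall confidence: logistic slope with subject intercepts.
consistency_slope <- function(table, z_crit, positive = TRUE) {
  d <- analysis_frame(table)
  d <- d[d$value_1 != d$value_2, ]
  d$correct <- as.integer(d$choice == ifelse(d$value_1 > d$value_2, 1L, 2L))
  d <- standardize_predictors(d, c("overall_conf", "abs_value_diff"))
  f <- stats::as.formula(paste("correct ~", subject_term(d),
                               "+ abs_value_diff + overall_conf"))
  fit <- suppressWarnings(glm(f, data = d, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-10,
                                                           maxit = 100)))
  ct <- coef_table(fit)
  z <- ct$z[ct$term == "overall_conf"]
  sig_row(NA, NA, z, if (positive) z >= z_crit else z <= -z_crit)
}

#' Sensitivity scan of the crossover signature over the parameter grid
#'
#' Re-simulates the design at every (beta_conf, cost) cell for the
#' requested variants and evaluates the crossover signature (a positive,
#' significant duration-by-overall-value interaction on choice). The
#' reference-dependent model should carry the signature at every cell; the
#' flat-prior model at none.
#'
#' @param study A [generate_study()] result (fixed design across cells).
#' @param beta_conf_values,cost_values Parameter values scanned.
#' @param variants Subset of `c("main", "zero_prior", "flat_prior",
#'   "equal_weight")`.
#' @param params_template [model_params()] supplying non-scanned fields.
#' @param n_reps Repetitions per trial per cell.
#' @param seed Root seed (shared substreams across cells).
#' @param z_crit Significance criterion.
#' @return Data frame `beta_conf`, `cost`, `variant`, `flag`, `value`
#'   (interaction z), `holds`.
#' @export
sensitivity_scan <- function(study, beta_conf_values, cost_values,
                             variants = c("main", "flat_prior"),
                             params_template = model_params(),
                             n_reps = 1, seed = 1L, z_crit = 1.96) {
  ratings <- study_ratings(study)
  out <- list()
  for (variant in variants) {
    pv <- switch(variant, main = "empirical", zero_prior = "zero",
                 flat_prior = "flat", equal_weight = "empirical")
    prec <- if (variant == "equal_weight") "equal_weight" else "veridical"
    prior <- fit_prior(ratings, pv, params_template$flat_lambda)
    for (b in beta_conf_values) for (cc in cost_values) {
      p <- params_template
      p$beta_conf <- b; p$cost <- cc
      p$prior_variant <- pv; p$precision_variant <- prec
      tab <- simulate_experiment(study$specs, prior, p, n_reps = n_reps,
                                 seed = seed)
      ct <- choice_regression(tab, terms = c("rel_value", "rel_duration",
                                             "overall_value",
                                             "rel_duration:overall_value"))
      z <- term_z(ct, "rel_duration:overall_value")
      out[[length(out) + 1L]] <- data.frame(
        beta_conf = b, cost = cc, variant = variant,
        flag = "dur_x_overall_value_pos", value = z,
        holds = z >= z_crit)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
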