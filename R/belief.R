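# Core generative and belief-updating machinery: Gaussian context priors,
# confidence-scaled sample precision, conjugate posterior updates, and the
# argmax decision rule.

#' Construct model parameters
#'
#' Bundles the free parameters and structural constants of the sequential
#' sampling model. The model has two free parameters: `beta_conf`, which maps
#' a 1-5 confidence rating onto the precision of momentary value samples
#' (precision per confidence unit), and `cost`, the linear time cost of
#' sampling in value units per second. Everything else is a structural
#' constant or a variant selector.
#'
#' @param beta_conf Precision gained per confidence unit (> 0). Together with
#'   a confidence rating `conf` it sets the sample precision `beta_conf * conf`.
#' @param cost Sampling cost in value units per second (>= 0).
#' @param beta_bias Additive precision offset used by the `"biased"`
#'   precision variant; positive values model overconfidence (the agent
#'   believes its samples are more precise than they are), negative values
#'   underconfidence.
#' @param dt_ms Time represented by one value sample, in ms. Defaults to 10.
#' @param deadline_ms Response deadline in ms. Defaults to 5000, giving a cap
#'   of `deadline_ms / dt_ms` = 500 samples per trial.
#' @param prior_variant One of `"empirical"` (Gaussian fit to the rating
#'   distribution), `"zero"` (prior mean pinned at 0), `"flat"`
#'   (near-zero prior precision, removing prior information).
#' @param precision_variant One of `"veridical"` (posterior uses the true
#'   sample precision), `"equal_weight"` (all items updated with the average
#'   precision), `"biased"` (updating precision offset by `beta_bias`).
#' @param flat_lambda Prior precision used by the flat-prior variant.
#' @param default_confidence Confidence imputed for items lacking a
#'   confidence rating (the average rating observed when confidence is
#'   measured, 4.18).
#' @return An object of class `model_params`.
#' @export
model_params <- function(beta_conf = 0.01, cost = 0.01, beta_bias = 0,
                         dt_ms = 10, deadline_ms = 5000,
                         prior_variant = c("empirical", "zero", "flat"),
                         precision_variant = c("veridical", "equal_weight", "biased"),
                         flat_lambda = 1e-6, default_confidence = 4.18) {
  prior_variant <- match.arg(prior_variant)
  precision_variant <- match.arg(precision_variant)
  if (!is.numeric(beta_conf) || beta_conf <= 0)
    stop("invalid parameter: beta_conf must be > 0")
  if (!is.numeric(cost) || cost < 0)
    stop("invalid parameter: cost must be >= 0")
  if (!is.numeric(dt_ms) || dt_ms <= 0)
    stop("invalid parameter: dt_ms must be > 0")
  if (!is.numeric(deadline_ms) || deadline_ms < dt_ms)
    stop("invalid parameter: deadline_ms must be >= dt_ms")
  if (!is.numeric(flat_lambda) || flat_lambda <= 0)
    stop("invalid parameter: flat_lambda must be > 0")
  structure(list(
    beta_conf = beta_conf, cost = cost, beta_bias = beta_bias,
    dt_ms = dt_ms, deadline_ms = deadline_ms,
    prior_variant = prior_variant, precision_variant = precision_variant,
    flat_lambda = flat_lambda, default_confidence = default_confidence
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (", x$prior_variant, " prior, ",
      x$precision_variant, " precision)\n", sep = "")
  cat(sprintf("  beta_conf = %g, cost = %g / s, beta_bias = %g\n",
              x$beta_conf, x$cost, x$beta_bias))
  cat(sprintf("  dt = %g ms, deadline = %g ms (cap %d samples)\n",
              x$dt_ms, x$deadline_ms, as.integer(x$deadline_ms / x$dt_ms)))
  invisible(x)
}

#' Fit a Gaussian context prior to a set of value ratings
#'
#' The agent's prior belief about any item's value is a Gaussian fit to the
#' empirical distribution of ratings in the current context:
#' `mu_prior = mean(ratings)`, `lambda_prior = sd(ratings)^-2` (population
#' standard deviation). The `"zero"` variant keeps the empirical precision
#' but pins the prior mean at 0 (the scale minimum); the `"flat"` variant
#' keeps the empirical mean but sets the prior precision to `flat_lambda`,
#' effectively removing prior information.
#'
#' @param ratings Numeric vector of value ratings (0-10 scale), length >= 2,
#'   not all identical.
#' @param variant `"empirical"`, `"zero"`, or `"flat"`.
#' @param flat_lambda Prior precision for the flat variant.
#' @return An object of class `prior_belief` with fields `mu_prior` and
#'   `lambda_prior`.
#' @examples
#' fit_prior(c(2, 4, 6, 8))              # mu 5, lambda 0.2
#' fit_prior(c(2, 4, 6, 8), "zero")      # mu 0, lambda 0.2
#' @export
fit_prior <- function(ratings, variant = c("empirical", "zero", "flat"),
                      flat_lambda = 1e-6) {
  variant <- match.arg(variant)
  ratings <- as.numeric(ratings)
  if (length(ratings) < 2)
    stop("degenerate prior: need at least 2 ratings to fit a prior")
  m <- mean(ratings)
  v <- mean((ratings - m)^2)  # population variance
  if (v <= 0)
    stop("degenerate prior: ratings have zero variance")
  if (!is.numeric(flat_lambda) || flat_lambda <= 0)
    stop("invalid parameter: flat_lambda must be > 0")
  out <- switch(variant,
    empirical = list(mu_prior = m, lambda_prior = 1 / v),
    zero      = list(mu_prior = 0, lambda_prior = 1 / v),
    flat      = list(mu_prior = m, lambda_prior = flat_lambda))
  out$variant <- variant
  structure(out, class = "prior_belief")
}

#' @export
print.prior_belief <- function(x, ...) {
  cat(sprintf("Gaussian prior (%s): mu = %.4g, lambda = %.4g (sd = %.4g)\n",
              x$variant, x$mu_prior, x$lambda_prior, 1 / sqrt(x$lambda_prior)))
  invisible(x)
}

#' Confidence-scaled sample precision
#'
#' Maps a confidence rating onto sample precision. The true (sampling)
#' precision of an item's value samples is always `beta_conf * conf`. The
#' precision the agent *assumes when updating* depends on the model variant:
#' the veridical model uses the true precision; the equal-weight model uses
#' the average precision `beta_conf * mean_conf`, discarding item-level
#' confidence; the biased model adds a fixed offset,
#' `beta_bias + beta_conf * conf`, modelling systematic over- or
#' underconfidence. Only the updating precision ever differs between
#' variants; the sampling distribution itself is identical across them.
#'
#' @param conf Confidence rating(s) in `[1, 5]`; `NA` entries are replaced by
#'   `params$default_confidence`.
#' @param params A [model_params()] object.
#' @param role `"sampling"` (true precision of the generative draw) or
#'   `"updating"` (precision assumed by the belief update).
#' @param mean_conf Average confidence across the item context; required for
#'   the equal-weight variant in the updating role.
#' @return Numeric vector of precisions, same length as `conf`.
#' @export
effective_precision <- function(conf, params,
                                role = c("sampling", "updating"),
                                mean_conf = NULL) {
  role <- match.arg(role)
  conf <- as.numeric(conf)
  conf[is.na(conf)] <- params$default_confidence
  if (any(conf < 1 | conf > 5))
    stop("invalid parameter: confidence ratings must lie in [1, 5]")
  tau <- if (role == "sampling") {
    params$beta_conf * conf
  } else {
    switch(params$precision_variant,
      veridical    = params$beta_conf * conf,
      equal_weight = {
        if (is.null(mean_conf) || !is.numeric(mean_conf) || mean_conf <= 0)
          stop("invalid parameter: equal_weight updating requires mean_conf > 0")
        rep(params$beta_conf * mean_conf, length(conf))
      },
      biased       = params$beta_bias + params$beta_conf * conf)
  }
  if (any(tau <= 0))
    stop("invalid parameter: non-positive effective precision")
  tau
}

#' Draw noisy value samples
#'
#' A momentary value sample for an attended item is a Gaussian draw centred
#' on the item's true (rated) value with variance `1 / tau_sampling`.
#'
#' @param true_value Item value(s) on the rating scale.
#' @param tau_sampling Sample precision(s), > 0.
#' @param n Number of draws per value (default 1 draw for each element of
#'   `true_value`).
#' @return Numeric vector of samples.
#' @export
draw_sample <- function(true_value, tau_sampling, n = length(true_value)) {
  if (any(tau_sampling <= 0))
    stop("invalid parameter: tau_sampling must be > 0")
  rnorm(n, mean = true_value, sd = 1 / sqrt(tau_sampling))
}

#' Initialize a posterior belief state from a prior
#'
#' Before any samples, the posterior over an item's value equals the prior:
#' `mu = mu_prior`, `lam = lambda_prior`, with zero samples taken.
#'
#' @param prior A [fit_prior()] object.
#' @return An object of class `posterior_state` with fields `n_samples`,
#'   `sample_mean`, `mu`, `lam`, plus the originating `mu_prior` and
#'   `lambda_prior`.
#' @export
posterior_init <- function(prior) {
  stopifnot(inherits(prior, "prior_belief"))
  structure(list(
    n_samples = 0L, sample_mean = NA_real_,
    mu = prior$mu_prior, lam = prior$lambda_prior,
    mu_prior = prior$mu_prior, lambda_prior = prior$lambda_prior
  ), class = "posterior_state")
}

#' Conjugate Gaussian posterior update
#'
#' Incorporates one value sample into a running belief. With `N` samples of
#' assumed precision `tau` and sample mean `xbar`, the posterior is
#' `lam = lambda_prior + N * tau` and
#' `mu = mu_prior + (N * tau / lam) * (xbar - mu_prior)`:
#' the posterior mean starts at the prior mean and is shifted toward the
#' sample mean in proportion to the accumulated sample precision
#' (precision-weighted updating). The sample mean is maintained with the
#' numerically stable incremental form, so iterating this update over a
#' sequence reproduces the batch formula exactly.
#'
#' @param state A `posterior_state`.
#' @param sample One value sample.
#' @param tau_updating Precision the agent assumes for the sample (> 0);
#'   see [effective_precision()].
#' @return The updated `posterior_state`.
#' @export
update_posterior <- function(state, sample, tau_updating) {
  stopifnot(inherits(state, "posterior_state"))
  if (!is.numeric(tau_updating) || tau_updating <= 0)
    stop("invalid parameter: tau_updating must be > 0")
  n <- state$n_samples + 1L
  xbar <- if (n == 1L) sample else
    state$sample_mean + (sample - state$sample_mean) / n
  lam <- state$lambda_prior + n * tau_updating
  mu <- state$mu_prior + (n * tau_updating / lam) * (xbar - state$mu_prior)
  state$n_samples <- n
  state$sample_mean <- xbar
  state$lam <- lam
  state$mu <- mu
  state
}

#' @export
print.posterior_state <- function(x, ...) {
  cat(sprintf("Posterior: N = %d, mu = %.4g, lam = %.4g (sample mean %.4g)\n",
              x$n_samples, x$mu, x$lam,
              if (x$n_samples) x$sample_mean else NA_real_))
  invisible(x)
}

#' Choose the item with maximal estimated value
#'
#' The decision rule selects whichever item has the largest posterior mean
#' at stopping time. Exact ties are broken uniformly at random.
#'
#' @param states List of `posterior_state` objects (or a numeric vector of
#'   posterior means).
#' @return The index of the chosen item.
#' @export
decide <- function(states) {
  mu <- if (is.numeric(states)) states
        else vapply(states, function(s) s$mu, numeric(1))
  best <- which(mu == max(mu))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}
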