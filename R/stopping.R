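# Approximate optimal stopping: the value of computation (VOC) for a coarse
# menu of candidate additional-sampling amounts, in the Directed Cognition
# family. The agent keeps sampling as long as some amount of additional
# sampling has expected decision-quality gain exceeding its linear time cost.

#' Standard deviation of the future posterior mean
#'
#' If an item's belief currently has precision `lam` and the agent plans
#' `h` more samples of assumed precision `tau_updating`, the posterior mean
#' after those samples is itself a random variable (a preposterior). Its
#' standard deviation is `sqrt(1/lam - 1/(lam + h * tau_updating))`: zero
#' for `h = 0`, increasing in `h`, and bounded by the current posterior SD
#' `sqrt(1/lam)`.
#'
#' @param lam Current posterior precision(s).
#' @param h Number of planned additional samples (>= 0).
#' @param tau_updating Assumed sample precision (> 0).
#' @return Standard deviation(s) of the future posterior mean.
#' @export
preposterior_sd <- function(lam, h, tau_updating) {
  stopifnot(all(h >= 0), all(lam > 0), all(tau_updating > 0))
  sqrt(pmax(0, 1 / lam - 1 / (lam + h * tau_updating)))
}

#' Expected gain in decision quality from additional sampling
#'
#' Given current posterior means `mu = (mu1, mu2)` and preposterior
#' standard deviations `sds = (s1, s2)` implied by a planned sample split,
#' the future posterior means are independent Gaussians centred on the
#' current means. The expected value of the then-chosen option is the
#' expected maximum of two independent Gaussians. The gain over the current
#' best, `E[max] - max(mu)`, has the closed form
#' `theta * dnorm(z) - |d| * pnorm(-z)` with `d = mu1 - mu2`,
#' `theta = sqrt(s1^2 + s2^2)` and `z = |d| / theta` (evaluated in this
#' cancellation-free form so it stays strictly positive whenever some
#' sampling is planned). It is always >= 0 and zero when no sampling is
#' planned.
#'
#' @param mu Length-2 vector of current posterior means.
#' @param sds Length-2 vector of preposterior standard deviations.
#' @return Expected improvement in the chosen option's value (>= 0).
#' @export
expected_max_gain <- function(mu, sds) {
  stopifnot(length(mu) == 2, length(sds) == 2, all(sds >= 0))
  theta <- sqrt(sds[1]^2 + sds[2]^2)
  if (theta == 0) return(0)
  z <- abs(mu[1] - mu[2]) / theta
  max(theta * dnorm(z) - abs(mu[1] - mu[2]) * pnorm(-z), 0)
}

#' Candidate menu of additional-sampling amounts
#'
#' A geometric menu 1, 2, 4, 8, ... capped at the samples remaining before
#' the deadline, plus the full remainder itself. A coarse geometric menu is
#' the standard Directed Cognition discretization: it keeps the stopping
#' assessment cheap while spanning short- and long-horizon plans.
#'
#' @param remaining Samples left before the deadline.
#' @return Increasing integer vector of candidate horizons (empty if
#'   `remaining` is 0).
#' @export
voc_menu <- function(remaining) {
  stopifnot(remaining >= 0)
  if (remaining < 1) return(integer(0))
  h <- 2^(0:ceiling(log2(max(remaining, 1))))
  as.integer(unique(c(h[h < remaining], remaining)))
}

#' Assess the value of computation and the stopping decision
#'
#' For every candidate horizon `h` in the menu, the planned samples are
#' split between the items according to their expected presentation-time
#' shares (the short-share item gets `round(h * share)`, the long item the
#' remainder), the expected decision-quality gain is computed via
#' [expected_max_gain()], and the linear time cost `cost * h * dt / 1000`
#' is subtracted. The agent continues while some candidate has non-negative
#' net value and stops once every candidate is strictly negative (or no
#' samples remain): under any positive cost the zero boundary has measure
#' zero, while under zero cost a vanishing (underflowed) gain still counts
#' as worth taking, so a free agent samples until the deadline.
#' Beliefs -- the possibly biased updating
#' precision -- drive the assessment: stopping is part of the agent's
#' inference and only has access to assumed precision.
#'
#' @param states List of two `posterior_state` objects.
#' @param params A [model_params()] object.
#' @param shares Length-2 vector of expected duration shares (sums to 1).
#' @param tau_updating Length-2 vector of assumed sample precisions.
#' @param remaining Samples left before the deadline (>= 0).
#' @return An object of class `voc_assessment` with fields `horizons`,
#'   `net_values`, and `stop` (`TRUE` iff all net values are < 0 or no
#'   samples remain).
#' @export
assess_voc <- function(states, params, shares, tau_updating, remaining) {
  stopifnot(length(states) == 2, length(shares) == 2,
            length(tau_updating) == 2, remaining >= 0)
  mu <- c(states[[1]]$mu, states[[2]]$mu)
  lam <- c(states[[1]]$lam, states[[2]]$lam)
  hs <- voc_menu(remaining)
  short <- if (shares[1] <= shares[2]) 1L else 2L
  long <- 3L - short
  net <- vapply(hs, function(h) {
    h_i <- integer(2)
    h_i[short] <- round(h * shares[short])
    h_i[long] <- h - h_i[short]
    sds <- preposterior_sd(lam, h_i, tau_updating)
    expected_max_gain(mu, sds) - params$cost * h * params$dt_ms / 1000
  }, numeric(1))
  structure(list(horizons = hs, net_values = net,
                 stop = remaining == 0 || all(net < 0)),
            class = "voc_assessment")
}
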