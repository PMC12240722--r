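test_that("prohibitive cost stops after the mandatory first sample", {
  set.seed(31)
  spec <- quick_spec()
  res <- simulate_trial(spec, fit_prior(c(3, 5, 7)), model_params(cost = 1e6))
  expect_equal(res$n_samples, 1L)
  expect_equal(res$rt_ms, 10)
  expect_false(res$aborted)
  expect_true(res$choice %in% 1:2)
})

test_that("zero cost samples to the deadline and aborts at the cap", {
  set.seed(32)
  spec <- quick_spec()
  res <- simulate_trial(spec, fit_prior(c(3, 5, 7)), model_params(cost = 0))
  expect_true(res$aborted)
  expect_equal(res$n_samples, 500L)   # 5 s deadline / 10 ms per sample
  expect_true(is.na(res$choice))
  expect_true(is.na(res$rt_ms))
})

test_that("trials are deterministic given a seed", {
  spec <- quick_spec()
  pr <- fit_prior(c(3, 5, 7))
  p <- model_params()
  set.seed(33); a <- simulate_trial(spec, pr, p)
  set.seed(33); b <- simulate_trial(spec, pr, p)
  expect_identical(a$choice, b$choice)
  expect_identical(a$n_samples, b$n_samples)
  expect_equal(sapply(a$states, `[[`, "mu"), sapply(b$states, `[[`, "mu"))
})

test_that("compiled kernel and R reference loop agree draw for draw", {
  pr <- fit_prior(c(3, 4, 5, 6, 7))
  for (variant in c("veridical", "equal_weight", "biased")) {
    p <- model_params(precision_variant = variant,
                      beta_bias = if (variant == "biased") 0.04 else 0)
    for (seed in 41:44) {
      spec <- quick_spec(v1 = 6.5, v2 = 4.5, c1 = 5, c2 = 3,
                         long_item = 1 + seed %% 2)
      set.seed(seed); a <- simulate_trial(spec, pr, p, engine = "cpp")
      set.seed(seed); b <- simulate_trial(spec, pr, p, engine = "r")
      expect_identical(a$choice, b$choice)
      expect_identical(a$n_samples, b$n_samples)
      expect_identical(a$aborted, b$aborted)
      expect_equal(sapply(a$states, `[[`, "mu"),
                   sapply(b$states, `[[`, "mu"), tolerance = 1e-12)
      expect_equal(sapply(a$states, `[[`, "lam"),
                   sapply(b$states, `[[`, "lam"), tolerance = 1e-12)
    }
  }
})

test_that("the VOC trace records every stopping assessment", {
  set.seed(34)
  res <- simulate_trial(quick_spec(), fit_prior(c(3, 5, 7)),
                        model_params(cost = 0.05), trace = TRUE)
  tr <- res$voc_trace
  expect_named(tr, c("step", "h", "net_value"))
  # one assessment per sample taken before the stop
  expect_equal(sort(unique(tr$step)), seq_len(res$n_samples))
  # the trial stopped because the last assessment was all-negative
  expect_true(all(tr$net_value[tr$step == res$n_samples] < 0))
  expect_true(all(tr$h >= 1))
})

test_that("RT equals samples times dt and precision bookkeeping is exact", {
  pr <- fit_prior(c(3, 5, 7))
  p <- model_params()
  set.seed(35)
  for (i in 1:10) {
    res <- simulate_trial(quick_spec(v1 = runif(1, 0, 10), v2 = runif(1, 0, 10)),
                          pr, p)
    if (!res$aborted) expect_equal(res$rt_ms / p$dt_ms, res$n_samples)
    expect_equal(sum(sapply(res$states, `[[`, "n_samples")), res$n_samples)
    for (s in res$states)
      expect_equal(s$lam - pr$lambda_prior,
                   s$n_samples * effective_precision(4, p, "updating"),
                   tolerance = 1e-12)
  }
})

test_that("experiments produce one tidy row per trial repetition", {
  set.seed(36)
  specs <- lapply(1:10, function(i)
    quick_spec(v1 = runif(1, 2, 8), v2 = runif(1, 2, 8),
               c1 = sample(1:5, 1), c2 = sample(1:5, 1),
               trial_id = i, subject_id = 1 + (i > 5)))
  pr <- fit_prior(c(3, 5, 7))
  tab <- simulate_experiment(specs, pr, model_params(), n_reps = 30, seed = 2)
  expect_equal(nrow(tab), 300)
  expect_equal(tab$rel_value, tab$value_1 - tab$value_2)
  expect_equal(tab$overall_value, (tab$value_1 + tab$value_2) / 2)
  expect_true(all(is.na(tab$rt_ms) | tab$rt_ms <= 5000))
  expect_true(all(tab$aborted == is.na(tab$choice)))
  # substreams keyed by (trial_id, rep): a trial simulated in isolation
  # reproduces its batch rows (veridical variant; no shared context)
  solo <- simulate_experiment(specs[3], pr, model_params(), n_reps = 30, seed = 2)
  batch_rows <- tab[tab$trial_id == 3, ]
  expect_equal(solo$choice, batch_rows$choice)
  expect_equal(solo$rt_ms, batch_rows$rt_ms)
})

test_that("summary statistics match a hand count", {
  tab <- data.frame(
    subject_id = 1, trial_id = 1:4, rep = 1,
    value_1 = c(6, 2, 5, 8), value_2 = c(2, 6, 5, 3),
    conf_1 = 4, conf_2 = 4,
    rel_value = c(4, -4, 0, 5), overall_value = c(4, 4, 5, 5.5),
    rel_duration_share = 5 / 7, first_item = 1, long_item = 1,
    choice = c(1L, 1L, 1L, 1L), rt_ms = c(400, 600, 500, 800),
    aborted = FALSE)
  class(tab) <- c("choice_table", "data.frame")
  s <- summary_stats(tab)
  expect_equal(s$accuracy, 2 / 3)     # equal-value row excluded
  expect_equal(s$median_rt_ms, 550)

  tab$aborted <- TRUE; tab$choice <- NA_integer_; tab$rt_ms <- NA_real_
  expect_error(summary_stats(tab), "insufficient data")

  one <- tab[4, ]; one$aborted <- FALSE; one$choice <- 1L; one$rt_ms <- 800
  expect_equal(summary_stats(one)$accuracy, 1)
})

test_that("choice consistency rises with sample precision at fixed cost", {
  st <- quick_study(n_subjects = 2, seed = 51)
  pr <- fit_prior(study_ratings(st))
  lo <- simulate_experiment(st$specs, pr, model_params(beta_conf = 0.002),
                            n_reps = 2, seed = 5)
  hi <- simulate_experiment(st$specs, pr, model_params(beta_conf = 0.05),
                            n_reps = 2, seed = 5)
  expect_gt(summary_stats(hi)$accuracy, summary_stats(lo)$accuracy)
})
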