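# A deterministic-looking table for regression mechanics (not a model run).
fake_table <- function(n = 600, seed = 81, subjects = 3) {
  set.seed(seed)
  d <- data.frame(
    subject_id = rep(seq_len(subjects), length.out = n),
    trial_id = seq_len(n), rep = 1L,
    value_1 = runif(n, 0, 10), value_2 = runif(n, 0, 10),
    conf_1 = sample(1:5, n, TRUE), conf_2 = sample(1:5, n, TRUE),
    rel_duration_share = sample(c(5 / 7, 2 / 7), n, TRUE),
    first_item = sample(1:2, n, TRUE), long_item = sample(1:2, n, TRUE),
    rt_ms = round(runif(n, 300, 3000) / 10) * 10,
    aborted = FALSE)
  d$rel_value <- d$value_1 - d$value_2
  d$overall_value <- (d$value_1 + d$value_2) / 2
  d$choice <- ifelse(d$rel_value > 0, 1L, 2L)
  class(d) <- c("choice_table", "data.frame")
  d
}

test_that("choice regression recovers a value-deterministic rule", {
  tab <- fake_table()
  ct <- choice_regression(tab)
  rv <- ct[ct$term == "rel_value", ]
  expect_gt(rv$estimate, 0)
  expect_equal(which.max(abs(ct$estimate)), which(ct$term == "rel_value"))
})

test_that("estimates are invariant to row duplication and row order", {
  tab <- fake_table(n = 400)
  noisy <- tab
  set.seed(82)
  flip <- runif(nrow(noisy)) < 0.25           # break separation
  noisy$choice[flip] <- 3L - noisy$choice[flip]
  a <- choice_regression(noisy)
  dup <- noisy[rep(seq_len(nrow(noisy)), 2), ]
  b <- choice_regression(dup)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-6)
  expect_true(all(b$se < a$se))
  shuffled <- noisy[sample(nrow(noisy)), ]
  c_ <- choice_regression(shuffled)
  expect_equal(a$estimate, c_$estimate, tolerance = 1e-8)
})

test_that("permuted choices fire significance at the nominal rate", {
  tab <- fake_table(n = 500, seed = 83)
  set.seed(84)
  hits <- replicate(60, {
    perm <- tab
    perm$choice <- sample(perm$choice)
    ct <- choice_regression(perm, terms = c("rel_duration", "overall_value",
                                            "rel_duration:overall_value"))
    abs(ct$z[ct$term == "rel_duration"]) > 1.96
  })
  expect_lt(mean(hits), 0.15)   # ~5% nominal
})

test_that("rt regression mechanics behave on constructed data", {
  tab <- fake_table(n = 500, seed = 85)
  flat <- tab; flat$rt_ms <- 1000
  ct <- rt_regression(flat)
  expect_true(all(abs(ct$estimate) < 1e-10))

  set.seed(86)
  gen <- tab
  gen$rt_ms <- exp(log(1000) - 0.1 * abs(gen$rel_value) + rnorm(nrow(gen), 0, 0.1))
  ct2 <- rt_regression(gen)
  slope <- ct2[ct2$term == "abs_value_diff", ]
  expect_lt(slope$z, -1.96)
  # standardized slope times sd gives back roughly the generating coefficient
  sc <- attr(ct2, "scaling")$abs_value_diff
  expect_lt(abs(slope$estimate / sc$scale - (-0.1)), 0.02)

  set.seed(87)
  zs <- replicate(40, {
    perm <- gen; perm$rt_ms <- sample(perm$rt_ms)
    ct3 <- rt_regression(perm)
    ct3$z[ct3$term == "abs_value_diff"]
  })
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("crossover point maps standardized coefficients to rating units", {
  mk <- function(b_main, b_int, center = 5, scale = 2) {
    ct <- data.frame(term = c("rel_duration", "rel_duration:overall_value"),
                     estimate = c(b_main, b_int), se = 0.1,
                     z = c(b_main, b_int) / 0.1)
    attr(ct, "scaling") <- list(overall_value = list(center = center,
                                                     scale = scale))
    ct
  }
  expect_equal(crossover_value(mk(0, 1)), 5)          # symmetric case
  expect_equal(crossover_value(mk(0.5, 1)), 5 - 0.5 * 2)
  expect_error(crossover_value(mk(0.5, 1e-12)), "undefined crossover")
})

test_that("signature evaluation rejects mismatched designs", {
  a <- fake_table(n = 200)
  b <- fake_table(n = 100)
  expect_error(qualitative_signature(list(main = a, flat_prior = b)),
               "incompatible")
  expect_error(qualitative_signature(list(biased = a)), "incompatible")
})

test_that("signature flags carry the expected structure on a model run", {
  st <- quick_study(n_subjects = 2, seed = 88)
  tab <- variant_table(st, "main", n_reps = 1, seed = 9)
  sig <- qualitative_signature(list(main = tab))
  expect_setequal(sig$flag[sig$variant == "main"],
                  c("dur_x_overall_value_pos", "dur_main_null",
                    "relconf_x_overall_value_pos", "overallconf_x_rel_value_pos",
                    "overallconf_rt_neg", "overallconf_consistency_pos"))
  expect_type(sig$holds, "logical")
  expect_true(all(is.finite(sig$value)))
})

test_that("sensitivity scans emit one row per cell and variant", {
  st <- quick_study(n_subjects = 1, seed = 89)
  scan <- sensitivity_scan(st, beta_conf_values = c(0.005, 0.05),
                           cost_values = c(0.005, 0.05),
                           variants = c("main", "flat_prior"),
                           n_reps = 1, seed = 10)
  expect_equal(nrow(scan), 2 * 2 * 2)
  expect_setequal(unique(scan$variant), c("main", "flat_prior"))
  expect_true(all(is.finite(scan$value)))
})
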