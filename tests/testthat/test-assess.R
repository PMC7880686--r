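test_that("bin summaries use equal-count bins with early remainder", {
  expect_equal(rleam:::bin_index(200, 10), rep(1:10, each = 20))
  idx <- rleam:::bin_index(23, 10)
  expect_equal(as.vector(table(idx)), c(3, 3, 3, 2, 2, 2, 2, 2, 2, 2))
  expect_equal(length(idx), 23L)
})

test_that("bin summaries match order-statistics oracles", {
  withr::with_seed(111, {
    tr <- tibble::tibble(
      subject = 1L, block = 1L, trial = 1:200, set_id = "s", cue = "none",
      choice = 1L, rt = rlnorm(200, -0.5, 0.4),
      outcome = 1L, reward = 1L, too_late = FALSE,
      correct = runif(200) < 0.8)
  })
  bs <- bin_summaries(tr, n_bins = 10)
  expect_equal(nrow(bs), 10L)
  expect_true(all(bs$n == 20))
  # oracle: direct sort-based percentiles on the first bin
  b1 <- tr[1:20, ]
  expect_equal(bs$accuracy[1], mean(b1$correct))
  rc <- b1$rt[b1$correct]
  expect_equal(bs$rt_correct_p10[1], sort_percentile(rc, 0.1))
  expect_equal(bs$rt_correct_p50[1], sort_percentile(rc, 0.5))
  expect_equal(bs$rt_correct_p90[1], sort_percentile(rc, 0.9))
  # percentiles are ordered wherever defined
  ok <- !is.na(bs$rt_correct_p10)
  expect_true(all(bs$rt_correct_p10[ok] <= bs$rt_correct_p50[ok]))
  expect_true(all(bs$rt_correct_p50[ok] <= bs$rt_correct_p90[ok]))
})

test_that("degenerate all-correct data yield accuracy 1 and missing error RTs", {
  tr <- tibble::tibble(
    subject = rep(1:2, each = 50), block = 1L, trial = rep(1:50, 2),
    set_id = "s", cue = "none", choice = 1L, rt = 0.5, outcome = 1L,
    reward = 1L, too_late = FALSE, correct = TRUE)
  bs <- bin_summaries(tr, n_bins = 5)
  expect_true(all(bs$accuracy == 1))
  expect_true(all(is.na(bs$rt_error_p50)))
  # fewer than 3 errors in a bin -> error percentiles stay missing
  tr$correct[c(3, 17)] <- FALSE
  bs2 <- bin_summaries(tr, n_bins = 5)
  expect_true(all(is.na(bs2$rt_error_p50)))
})

test_that("reversal alignment re-indexes trials without changing them", {
  d <- make_design("exp3", seed = 112)
  m <- model_spec("rl_ard")
  p <- c(alpha = 0.35, a = 1.48, t0 = 0.13, V0 = 1.86, wd = 1.52, ws = 0.23)
  sim <- simulate_experiment(d, m, p, n_subjects = 2, seed = 113)
  al <- reversal_align(sim, d)
  expect_equal(nrow(al), nrow(sim))
  expect_setequal(al$trial, sim$trial)
  # trial at the reversal maps to 0, the one before to -1
  rv1 <- d$reversals$reversal_trial[1]
  blk1 <- al[al$block == 1 & al$subject == 1, ]
  blk1 <- blk1[order(blk1$trial), ]
  expect_equal(blk1$rel_trial, seq_len(128) - rv1)
  expect_equal(blk1$rel_trial[rv1], 0L)
  expect_equal(blk1$rel_trial[rv1 - 1], -1L)
  # choice_a flags the pre-reversal high-probability option
  expect_equal(al$choice_a, al$choice == 1L)
  expect_error(reversal_align(sim, make_design("exp1", seed = 114)),
               "no reversals")
})

test_that("exclusion screening applies the paradigm cutoffs and binomial test", {
  mk <- function(subject, acc, n = 208) tibble::tibble(
    subject = subject, trial = 1:n, correct = rep(c(TRUE, FALSE),
                                                  c(round(acc * n), n - round(acc * n))))
  tr <- dplyr::bind_rows(mk(1, 0.9), mk(2, 0.5), mk(3, 0.58))
  scr <- exclusion_screen(tr, n_options = 2)
  expect_equal(scr$keep, c(TRUE, FALSE, TRUE))
  scr_b <- exclusion_screen(tr, n_options = 2, method = "binomial")
  expect_equal(scr_b$keep, c(TRUE, FALSE, TRUE))
  # the conventional cutoff and the exact test disagree in a narrow band
  tr56 <- mk(4, 0.56)
  expect_true(exclusion_screen(tr56, 2)$keep)
  expect_false(exclusion_screen(tr56, 2, method = "binomial")$keep)
  # the exact binomial criterion at n = 208 sits close to the 0.55 cutoff
  crit <- (qbinom(0.95, 208, 0.5) + 1) / 208
  expect_lt(abs(crit - 0.55), 0.03)
  # three-alternative default cutoff
  tr3 <- dplyr::bind_rows(mk(1, 0.36, 432), mk(2, 0.40, 432))
  scr3 <- exclusion_screen(tr3, n_options = 3)
  expect_equal(scr3$keep, c(FALSE, TRUE))
})

test_that("posterior predictive envelopes are seeded and cover the data source", {
  env <- small_ard_fit()
  ppc <- posterior_predict(env$fit, env$design, n_draws = 20, seed = 115)
  ppc2 <- posterior_predict(env$fit, env$design, n_draws = 20, seed = 115)
  expect_identical(ppc$envelope, ppc2$envelope)
  expect_true(all(ppc$envelope$lower <= ppc$envelope$upper, na.rm = TRUE))
  # a single draw collapses the envelope onto that draw
  p1 <- posterior_predict(env$fit, env$design, n_draws = 1, seed = 116)
  expect_equal(p1$envelope$lower, p1$envelope$upper)
  expect_equal(p1$envelope$lower, p1$envelope$median)
  # the observed (generating) data largely fall inside the 95% envelopes
  obs <- bin_summaries(env$sim)
  long <- tidyr::pivot_longer(obs, -c(bin, n), names_to = "statistic",
                              values_to = "value")
  joined <- dplyr::inner_join(long, ppc$envelope, by = c("bin", "statistic"))
  joined <- joined[is.finite(joined$value) & is.finite(joined$lower), ]
  inside <- mean(joined$value >= joined$lower & joined$value <= joined$upper)
  expect_gt(inside, 0.7)
})

test_that("autoplot methods return ggplot objects", {
  env <- small_ard_fit()
  bs <- bin_summaries(env$sim)
  expect_s3_class(autoplot(bs), "ggplot")
  expect_s3_class(autoplot(env$fit), "ggplot")
  ppc <- posterior_predict(env$fit, env$design, n_draws = 5, seed = 117,
                           observed = env$sim)
  expect_s3_class(autoplot(ppc), "ggplot")
})

test_that("recovery harness reports rank correlations per parameter", {
  m <- model_spec("softmax")
  d <- make_design("exp1", seed = 118)
  rec <- recovery_study(m, d, n_subjects = 8, seed = 119,
                        group = tibble::tibble(param = c("alpha", "beta"),
                                               mean = c(0.3, 3), sd = c(0.1, 1)),
                        config = sampler_config(n_burn = 150, n_sample = 250,
                                                n_init = 100, max_extend = 0))
  expect_setequal(rec$correlations$param, c("alpha", "beta"))
  expect_true(all(is.finite(rec$correlations$cor_spearman)))
  # the soft-max parameters are well identified from 208 choices
  expect_gt(min(rec$correlations$cor_spearman), 0.5)
  expect_s3_class(autoplot(rec), "ggplot")
  expect_equal(tidy(rec), rec$correlations)
})
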