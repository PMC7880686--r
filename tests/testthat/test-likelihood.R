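test_that("model specs expose the registered free-parameter sets", {
  expect_equal(model_spec("rl_ddm")$n_free, 4L)
  expect_equal(model_spec("rl_rd")$n_free, 5L)
  expect_equal(model_spec("rl_lard")$n_free, 5L)
  expect_equal(model_spec("rl_ard")$n_free, 6L)
  expect_equal(model_spec("rl_ard_winall")$n_free, 6L)
  expect_equal(model_spec("rl_ard_winall")$n_accumulators, 6L)
  expect_equal(model_spec("rl_ard_winall")$n_options, 3L)
  expect_equal(model_spec("softmax")$n_free, 2L)
  # diffusion variability variants
  expect_equal(model_spec("rl_ddm", nonlinear = TRUE)$n_free, 5L)
  expect_equal(model_spec("rl_ddm", sv = TRUE, sz = TRUE)$n_free, 6L)
  expect_equal(model_spec("rl_ddm", sv = TRUE, sz = TRUE, st0 = TRUE)$n_free, 7L)
  expect_equal(model_spec("rl_ddm", nonlinear = TRUE, sv = TRUE, sz = TRUE,
                          st0 = TRUE)$n_free, 8L)
  expect_error(model_spec("rl_ard", sv = TRUE), "DDM")
  # condition multipliers add one parameter each
  expect_equal(model_spec("rl_ard", condition_vary = c("a", "V0", "v"))$n_free, 9L)
})

test_that("softmax log-likelihood has the closed uniform-choice form", {
  tr <- toy_trials(n = 24)
  m <- model_spec("softmax")
  ll <- log_likelihood_subject(tr, m, c(alpha = 0.2, beta = 0))
  expect_equal(ll, 24 * log(0.5))
})

test_that("race log-likelihood composes Q-trajectories with trial densities", {
  tr <- toy_trials(n = 12)
  m <- model_spec("rl_ard")
  ll <- log_likelihood_subject(tr, m, ard_params)
  # oracle: explicit per-trial density calls
  qt <- q_trajectory(tr, ard_params["alpha"])
  v <- drift_ard2(cbind(qt$q1, qt$q2), ard_params["V0"], ard_params["wd"],
                  ard_params["ws"])
  dens <- drace2(tr$rt, tr$choice, v[, 1], v[, 2], ard_params["a"],
                 ard_params["t0"])
  expect_equal(ll, sum(log(pmax(dens, 1e-10))), tolerance = 1e-10)
  # additivity: duplicating the data doubles the log-likelihood
  tr2 <- dplyr::mutate(dplyr::bind_rows(tr, tr), trial = dplyr::row_number())
  # (second copy restarts learning only if Q were reset; use two subjects instead)
  ll2 <- log_likelihood_subject(tr, m, ard_params) +
    log_likelihood_subject(tr, m, ard_params)
  expect_equal(ll2, 2 * ll)
})

test_that("responses faster than t0 are floored, not fatal", {
  tr <- toy_trials(n = 5)
  tr$rt <- 0.05  # below t0 = 0.11
  m <- model_spec("rl_ard")
  ll <- log_likelihood_subject(tr, m, ard_params)
  expect_true(is.finite(ll))
  expect_equal(ll, 5 * log(1e-10))
})

test_that("chain-vectorized likelihood equals scalar evaluation per row", {
  tr <- toy_trials(n = 40, seed = 77)
  for (arch in c("rl_ddm", "rl_rd", "rl_lard", "rl_ard", "softmax")) {
    m <- model_spec(arch)
    prep <- rleam:::prep_subject(tr, m)
    withr::with_seed(78, {
      pri <- default_priors(m)
      th <- sapply(seq_len(m$n_free), function(p)
        rleam:::rtnorm(6, pri$mean[p], pri$sd[p] / 4, pri$lb[p], pri$ub[p]))
      th <- matrix(th, 6, m$n_free, dimnames = list(NULL, m$params))
    })
    ll_vec <- rleam:::loglik_chains(prep, th, m)
    for (i in 1:6) {
      pars <- th[i, ]
      pars["alpha"] <- pnorm(pars["alpha"])
      expect_equal(log_likelihood_subject(tr, m, pars), ll_vec[i],
                   tolerance = 1e-10)
    }
  }
})

test_that("three-alternative likelihood uses the Win-All density", {
  withr::with_seed(79, {
    tr <- tibble::tibble(
      subject = 1L, block = 1L, trial = 1:15, set_id = "t1", cue = "none",
      choice = sample(1:3, 15, replace = TRUE), rt = runif(15, 0.3, 1.5),
      outcome = sample(0:1, 15, replace = TRUE), reward = 0L, too_late = FALSE)
  })
  m <- model_spec("rl_ard_winall")
  p <- c(alpha = 0.1, a = 1.6, t0 = 0.07, V0 = 1.14, wd = 1.6, ws = 0.15)
  ll <- log_likelihood_subject(tr, m, p)
  qt <- q_trajectory(tr, p["alpha"], n_options = 3)
  dens <- vapply(1:15, function(i) {
    v6 <- drift_ard_multi(unlist(qt[i, c("q1", "q2", "q3")]), p["V0"],
                          p["wd"], p["ws"])
    dwinall(tr$rt[i], tr$choice[i], v6, p["a"], p["t0"])
  }, numeric(1))
  expect_equal(ll, sum(log(pmax(dens, 1e-10))), tolerance = 1e-10)
})

test_that("condition mapping scales parameters proportionally on speed trials", {
  base <- c(a = 1.82, V0 = 2.5, m_a = -0.4286, m_V0 = 0.2, m_v = 0.1)
  expect_equal(map_conditions(base, c("a", "V0", "v"), "ACC")[["a"]], 1.82)
  expect_equal(map_conditions(base, c("a", "V0", "v"), "ACC")[["v_mult"]], 1)
  spd <- map_conditions(base, c("a", "V0", "v"), "SPD")
  expect_equal(spd[["a"]], 1.04, tolerance = 1e-3)
  expect_equal(spd[["V0"]], 3.0)
  expect_equal(spd[["v_mult"]], 1.1)
  expect_equal(map_conditions(c(a = 2, m_a = 0), "a", "SPD")[["a"]], 2)
  expect_error(map_conditions(c(a = 2, m_a = -1.2), "a", "SPD"), "-1")
  # boundary: multiplier near -1 sends the scaled value to 0+
  expect_equal(map_conditions(c(a = 2, m_a = -1 + 1e-9), "a", "SPD")[["a"]],
               2e-9, tolerance = 1e-6)
})

test_that("speed-condition multipliers enter the likelihood on cued trials only", {
  tr <- toy_trials(n = 20)
  tr$cue <- rep(c("SPD", "ACC"), 10)
  m <- model_spec("rl_ard", condition_vary = "a")
  p <- c(ard_params, m_a = -0.3)
  ll <- log_likelihood_subject(tr, m, p)
  # oracle: evaluate with per-trial thresholds
  qt <- q_trajectory(tr, p[["alpha"]])
  v <- drift_ard2(cbind(qt$q1, qt$q2), p[["V0"]], p[["wd"]], p[["ws"]])
  a_eff <- ifelse(tr$cue == "SPD", 0.7 * p[["a"]], p[["a"]])
  dens <- drace2(tr$rt, tr$choice, v[, 1], v[, 2], a_eff, p[["t0"]])
  expect_equal(ll, sum(log(pmax(dens, 1e-10))), tolerance = 1e-10)
  # with m_a = 0 the model collapses to the unconditioned one
  p0 <- c(ard_params, m_a = 0)
  expect_equal(log_likelihood_subject(tr, m, p0),
               log_likelihood_subject(tr, model_spec("rl_ard"), ard_params))
})

test_that("diffusion variability variants reduce to the base likelihood", {
  tr <- toy_trials(n = 15, seed = 80)
  base <- c(alpha = 0.14, a = 1.48, t0 = 0.25, w = 3.21)
  ll0 <- log_likelihood_subject(tr, model_spec("rl_ddm"), base)
  m3 <- model_spec("rl_ddm", sv = TRUE, sz = TRUE, st0 = TRUE)
  ll3 <- log_likelihood_subject(tr, m3, c(base, sv = 1e-9, sz = 1e-9, st0 = 1e-9))
  expect_equal(ll3, ll0, tolerance = 1e-6)
  # non-linear link with a high ceiling approximates the linear one at small w*dq
  m1 <- model_spec("rl_ddm", nonlinear = TRUE)
  ll1 <- log_likelihood_subject(tr, m1, c(alpha = 0.14, a = 1.48, t0 = 0.25,
                                          w = 2 * 3.21 / 1e4, vmax = 1e4))
  expect_equal(ll1, ll0, tolerance = 1e-3)
})

test_that("trials without a recorded response teach but add no density", {
  tr <- toy_trials(n = 10)
  tr_missing <- tr
  tr_missing$rt[4] <- NA
  m <- model_spec("rl_ard")
  ll_full <- log_likelihood_subject(tr, m, ard_params)
  ll_miss <- log_likelihood_subject(tr_missing, m, ard_params)
  # the missing trial's density is gone but its Q-update remains
  qt <- q_trajectory(tr_missing, ard_params["alpha"])
  v <- drift_ard2(cbind(qt$q1, qt$q2), ard_params["V0"], ard_params["wd"],
                  ard_params["ws"])
  keep <- !is.na(tr_missing$rt)
  dens <- drace2(tr_missing$rt[keep], tr_missing$choice[keep],
                 v[keep, 1], v[keep, 2], ard_params["a"], ard_params["t0"])
  expect_equal(ll_miss, sum(log(pmax(dens, 1e-10))))
  expect_false(isTRUE(all.equal(ll_full, ll_miss)))
})
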