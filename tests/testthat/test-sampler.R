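test_that("Gelman-Rubin diagnostic separates converged from split chains", {
  withr::with_seed(91, {
    dup <- array(NA_real_, c(400, 3, 2))  # identical chains per parameter
    for (p in 1:2) dup[, , p] <- rnorm(400)
    gr <- gelman_rubin(dup)
    expect_true(all(gr$psrf <= 1 + 1e-8))
    shifted <- array(rnorm(400 * 3 * 2), c(400, 3, 2))
    shifted[, 2, ] <- shifted[, 2, ] + 5  # one chain displaced by 5 SD
    gr2 <- gelman_rubin(shifted)
    expect_true(all(gr2$psrf > 1.1))
    expect_gt(gr2$mpsrf, 1.1)
  })
  expect_error(gelman_rubin(matrix(1:2, 1, 2)), "at least 2")
})

test_that("Gelman-Rubin matches the reference implementation", {
  skip_if_not_installed("coda")
  withr::with_seed(92, {
    x <- array(rnorm(300 * 4 * 3, sd = rep(c(1, 1.3, 0.7), each = 300 * 4)),
               c(300, 4, 3))
    x[, 2, 1] <- x[, 2, 1] + 0.4
    gr <- gelman_rubin(x)
    ml <- coda::mcmc.list(lapply(1:4, function(ch) coda::mcmc(x[, ch, ])))
    ref <- coda::gelman.diag(ml, autoburnin = FALSE, transform = FALSE)
    expect_equal(unname(gr$psrf), unname(ref$psrf[, 1]), tolerance = 1e-8)
    expect_equal(gr$mpsrf, ref$mpsrf, tolerance = 1e-8)
  })
})

test_that("with no informative trials the sampler reproduces its priors", {
  # all responses missing: the likelihood is flat, so group-level draws must
  # match the prior (closed-form truncated-normal / gamma moments)
  trials <- tibble::tibble(
    subject = rep(1:3, each = 8), block = 1L, trial = rep(1:8, 3),
    set_id = "s", cue = "none", choice = NA_integer_, rt = NA_real_,
    outcome = NA_integer_, reward = NA_integer_, too_late = TRUE)
  m <- model_spec("softmax")
  pri <- default_priors(m)
  pri$mean <- c(0, 1); pri$sd <- c(1, 1)   # narrow priors for a fast check
  # chains over a flat likelihood mix slowly (group and subject states are
  # strongly coupled), so moments are pooled over seeds with Monte-Carlo
  # tolerances
  draws <- lapply(c(93, 193, 293), function(sd_) {
    fit <- run_sampler(trials, m, priors = pri,
                       config = sampler_config(n_burn = 500, n_sample = 3000,
                                               n_init = 50, max_extend = 0),
                       seed = sd_)
    list(mu_alpha = as.vector(fit$draws$mu[, , 1]),
         mu_beta = as.vector(fit$draws$mu[, , 2]),
         sig_alpha = as.vector(fit$draws$sigma[, , 1]))
  })
  mu_alpha <- unlist(lapply(draws, `[[`, "mu_alpha"))
  mu_beta <- unlist(lapply(draws, `[[`, "mu_beta"))
  sig_alpha <- unlist(lapply(draws, `[[`, "sig_alpha"))
  # alpha hypermean prior: plain normal(0, 1)
  expect_lt(abs(mean(mu_alpha) - 0), 0.35)
  expect_lt(abs(sd(mu_alpha) - 1), 0.3)
  # beta hypermean prior: normal(1, 1) truncated at 0
  tn_mean <- 1 + dnorm(-1) / (1 - pnorm(-1))
  expect_lt(abs(mean(mu_beta) - tn_mean), 0.35)
  expect_true(all(mu_beta >= 0))
  # hyper-SD prior: Gamma(1, 1), mean 1
  expect_lt(abs(mean(sig_alpha) - 1), 0.3)
})

test_that("the fit pipeline is deterministic per seed", {
  trials <- simulate_experiment(make_design("exp1", seed = 94),
                                model_spec("softmax"),
                                c(alpha = 0.2, beta = 3), n_subjects = 2,
                                seed = 95)
  m <- model_spec("softmax")
  cfg <- sampler_config(n_burn = 30, n_sample = 40, n_init = 20, max_extend = 0)
  f1 <- run_sampler(trials, m, config = cfg, seed = 96)
  f2 <- run_sampler(trials, m, config = cfg, seed = 96)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_sampler(trials, m, config = cfg, seed = 97)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a zero-iteration run returns the initial state unchanged", {
  trials <- simulate_experiment(make_design("exp1", seed = 98),
                                model_spec("softmax"),
                                c(alpha = 0.2, beta = 3), seed = 99)
  m <- model_spec("softmax")
  fit <- run_sampler(trials, m,
                     config = sampler_config(n_burn = 0, n_sample = 0,
                                             n_init = 0, max_extend = 0),
                     seed = 100)
  expect_equal(dim(fit$draws$mu)[1], 1L)
  expect_true(all(is.finite(fit$draws$loglik)))
  # initial states are shrunk prior draws: all within the prior support
  pri <- default_priors(m)
  for (p in seq_len(m$n_free)) {
    expect_true(all(fit$draws$theta[, , , p] >= pri$lb[p] &
                      fit$draws$theta[, , , p] <= pri$ub[p]))
  }
})

test_that("group posteriors recover generating group parameters", {
  env <- small_ard_fit()
  fit <- env$fit
  tid <- tidy(fit)
  est <- function(term) tid$estimate[tid$term == term]
  # group means land near the generating group values (loose: 5 subjects)
  expect_lt(abs(est("mu_a") - mean(env$gen$a)), 0.5)
  expect_lt(abs(est("mu_t0") - mean(env$gen$t0)), 0.08)
  expect_lt(abs(est("mu_V0") - mean(env$gen$V0)), 0.8)
  expect_true(est("mu_alpha") > 0.02 && est("mu_alpha") < 0.5)
  g <- glance(fit)
  expect_equal(g$n_subjects, 5L)
  expect_equal(g$n_free, 6L)
  expect_true(is.finite(g$bpic))
})

test_that("BPIC penalizes only posterior spread", {
  env <- small_ard_fit()
  fit <- env$fit
  b <- bpic(fit)
  expect_gt(b$pd, 0)
  expect_equal(b$bpic, b$dbar + 2 * b$pd)
  # degenerate posterior: freeze all draws at the posterior mean
  fit2 <- fit
  thbar <- apply(fit$draws$theta, c(3, 4), mean)
  for (s in seq_len(dim(fit$draws$theta)[3])) {
    for (p in seq_len(dim(fit$draws$theta)[4])) {
      fit2$draws$theta[, , s, p] <- thbar[s, p]
    }
  }
  colnames(thbar) <- fit$params
  llbar <- sum(vapply(seq_along(fit$preps), function(s)
    rleam:::loglik_chains(fit$preps[[s]], thbar[s, , drop = FALSE], fit$model),
    numeric(1)))
  fit2$draws$loglik[] <- llbar
  b2 <- bpic(fit2)
  expect_equal(b2$pd, 0, tolerance = 1e-8)
  expect_equal(b2$bpic, b2$dhat, tolerance = 1e-8)
})

test_that("model comparison table is ordered by BPIC", {
  env <- small_ard_fit()
  fit <- env$fit
  tab <- compare_models(ard = fit, also_ard = fit)
  expect_equal(tab$delta_bpic, c(0, 0))
  expect_equal(nrow(tab), 2L)
})
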