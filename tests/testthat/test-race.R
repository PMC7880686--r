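test_that("drift construction matches the linking equations", {
  # independent race: V0 + w * Q
  expect_equal(drift_rd(c(0.8, 0.2), V0 = 1.92, w = 3.09), c(4.392, 2.538))
  expect_equal(drift_rd(c(0.4, 0.4), V0 = 2, w = 0), c(2, 2))
  # two-alternative advantage race at reference parameter values
  v <- drift_ard2(c(0.8, 0.2), V0 = 2.46, wd = 2.25, ws = 0.36)
  expect_equal(unname(v), c(4.17, 1.47))
  # advantage term cancels for equal values: both drifts V0 + 2 ws Q
  v_eq <- drift_ard2(c(0.3, 0.3), V0 = 1, wd = 5, ws = 0.4)
  expect_equal(unname(v_eq), rep(1 + 2 * 0.4 * 0.3, 2))
  # ws = 0 is the limited variant: difference only
  expect_equal(drift_ard2(c(0.7, 0.1), 2, 1.5, 0),
               c(2 + 1.5 * 0.6, 2 - 1.5 * 0.6), ignore_attr = TRUE)
})

test_that("difference/sum and excitation/inhibition parametrizations coincide", {
  withr::with_seed(31, {
    for (i in 1:30) {
      q <- runif(2); V0 <- runif(1, 0, 4); wd <- rnorm(1, 2, 1); ws <- rnorm(1, 0, 1)
      expect_equal(drift_ard2(q, V0, wd, ws),
                   drift_ard2_ei(q, V0, we = wd + ws, wi = wd - ws),
                   tolerance = 1e-12)
    }
  })
})

test_that("six-accumulator drifts are label-equivariant and reduce to two-choice", {
  v <- drift_ard_multi(c(0.8, 0.25, 0.25), V0 = 1.14, wd = 1.6, ws = 0.15)
  expect_equal(unname(v[c("1-2", "1-3")]), rep(2.1775, 2))
  # all equal Q: all six drifts equal
  v_eq <- drift_ard_multi(rep(0.4, 3), 1, 2, 0.3)
  expect_true(all(abs(v_eq - v_eq[1]) < 1e-12))
  # permuting option labels permutes drifts identically
  q <- c(0.7, 0.2, 0.5); perm <- c(2, 3, 1)
  v1 <- drift_ard_multi(q, 1.2, 1.8, 0.2)
  v2 <- drift_ard_multi(q[perm], 1.2, 1.8, 0.2)
  relab <- function(lab) {
    ij <- as.integer(strsplit(lab, "-")[[1]])
    paste0(match(ij[1], perm), "-", match(ij[2], perm))
  }
  for (lab in names(v1)) expect_equal(unname(v2[relab(lab)]), unname(v1[lab]))
  # pairs (1-2, 2-1) alone reproduce the two-choice drifts
  q2 <- c(0.6, 0.15)
  v6 <- drift_ard_multi(c(q2, 0), 1.5, 2.1, 0.4)
  expect_equal(unname(v6[c("1-2", "2-1")]),
               unname(drift_ard2(q2, 1.5, 2.1, 0.4)))
  expect_error(drift_ard_multi(c(0.5, 0.5), 1, 1, 0), "ncol")
})

test_that("two-accumulator race density normalizes to choice probabilities", {
  # exchangeable accumulators: equal probabilities
  pr <- race_choice_prob(c(2, 2), a = 1.5, "race2")
  expect_equal(pr, c(0.5, 0.5), tolerance = 1e-6)
  # all-positive drifts: total mass 1
  pr2 <- race_choice_prob(c(4.17, 1.47), a = 2.14, "race2")
  expect_equal(sum(pr2), 1, tolerance = 1e-6)
  # one negative drift still yields a certain response (the other finishes)
  pr_mix <- race_choice_prob(c(1.5, -0.8), a = 1.2, "race2")
  expect_equal(sum(pr_mix), 1, tolerance = 1e-6)
  # all-negative drifts: defective (the race can stall)
  pr3 <- race_choice_prob(c(-0.5, -0.8), a = 1.2, "race2")
  expect_lt(sum(pr3), 0.99)
  # losing drift -> -Inf: density equals the plain shifted Wald density
  tg <- c(0.3, 0.8, 1.5)
  expect_equal(drace2(tg + 0.11, 1, 2, -60, 1.5, 0.11),
               dwald(tg, 1.5, 2), tolerance = 1e-10)
  expect_equal(drace2(0.05, 1, 2, 1, 1.5, 0.11), 0)  # rt <= t0
})

test_that("race density matches seeded Monte-Carlo winner frequencies", {
  withr::with_seed(32, {
    n <- 1e5
    v <- c(4.17, 1.47); a <- 2.14; t0 <- 0.11
    sim <- rrace(n, v, a, t0)
    pr <- race_choice_prob(v, a, "race2")
    expect_lt(abs(mean(sim$choice == 1) - pr[1]), 3 * se_prop(pr[1], n))
    # 10/50/90 percentiles of choice-1 RTs vs analytic conditional CDF
    tg <- seq(1e-4, 8, length.out = 8000)
    dens <- drace2(tg + t0, 1, v[1], v[2], a, t0)
    cdf <- cumsum(dens) * (tg[2] - tg[1]); cdf <- cdf / max(cdf)
    rt1 <- sim$rt[sim$choice == 1] - t0
    n1 <- length(rt1)
    for (p in c(0.1, 0.5, 0.9)) {
      q_an <- approx(cdf, tg, p, ties = "ordered")$y
      f_q <- dens[which.min(abs(tg - q_an))] / pr[1]
      se_q <- sqrt(p * (1 - p) / n1) / f_q
      expect_lt(abs(sort_percentile(rt1, p) - q_an), 3 * se_q)
    }
  })
})

test_that("race sampler agrees with the Euler-path oracle", {
  withr::with_seed(33, {
    n <- 5e3
    v <- c(3, 1.2); a <- 1.6; t0 <- 0.1
    exact <- rrace(n, v, a, t0)
    euler <- rrace_euler(n, v, a, t0, dt = 1e-3)
    p_ex <- mean(exact$choice == 1)
    p_eu <- mean(euler$choice == 1)
    expect_lt(abs(p_ex - p_eu), 4 * se_prop(0.8, n))
    expect_lt(abs(median(exact$rt) - median(euler$rt)), 0.02)
  })
})

test_that("Win-All density is symmetric, normalized, and matches Monte Carlo", {
  # symmetric drifts: one third each
  pw <- race_choice_prob(rep(2, 6), a = 1.6, "winall")
  expect_equal(pw, rep(1 / 3, 3), tolerance = 1e-6)
  # arbitrary positive drifts integrate to 1 over options
  v6 <- drift_ard_multi(c(0.8, 0.25, 0.25), 1.14, 1.6, 0.15)
  pw2 <- race_choice_prob(v6, a = 1.6, "winall")
  expect_equal(sum(pw2), 1, tolerance = 1e-6)
  expect_error(dwinall(0.5, 1, rep(1, 4), 1, 0.1), "six")

  withr::with_seed(34, {
    n <- 1e5
    a <- 1.6; t0 <- 0.07
    sim <- rrace(n, v6, a, t0)   # slower-of-the-two-winners stopping rule
    for (i in 1:3) {
      expect_lt(abs(mean(sim$choice == i) - pw2[i]), 3 * se_prop(pw2[i], n))
    }
    # RT percentiles for the winning option
    tg <- seq(1e-4, 8, length.out = 8000)
    dens <- dwinall(tg + t0, 1, v6, a, t0)
    cdf <- cumsum(dens) * (tg[2] - tg[1]); cdf <- cdf / max(cdf)
    rt1 <- sim$rt[sim$choice == 1] - t0
    for (p in c(0.1, 0.5, 0.9)) {
      q_an <- approx(cdf, tg, p, ties = "ordered")$y
      f_q <- dens[which.min(abs(tg - q_an))] / pw2[1]
      se_q <- sqrt(p * (1 - p) / length(rt1)) / f_q
      expect_lt(abs(sort_percentile(rt1, p) - q_an), 3 * se_q)
    }
  })
})

test_that("defective mass under negative drifts matches stalling frequency", {
  withr::with_seed(35, {
    n <- 1e5
    v <- c(-0.5, -1.2); a <- 1
    pr <- race_choice_prob(v, a, "race2")
    sim <- rrace(n, v, a, 0.1)
    p_resp <- mean(!is.na(sim$choice))
    expect_lt(abs(p_resp - sum(pr)), 3 * se_prop(sum(pr), n))
  })
})

test_that("non-decision variability preserves total probability mass", {
  v <- c(3, 1); a <- 1.5; t0 <- 0.2; st0 <- 0.3
  tot <- sum(vapply(1:2, function(ch)
    integrate(function(t) drace2(t, ch, v[1], v[2], a, t0, st0), t0, Inf,
              rel.tol = 1e-8)$value, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-6)
})
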